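#' Treatment efficacy
#'
#' Percent reduction of tumor volume relative to the untreated control,
#' `(vol_control - vol_treated) / vol_control * 100`, both volumes taken at
#' the last day of treatment. Negative values mean the treated tumor is
#' larger than the control (hyperprogression).
#'
#' @param vol_control control tumor volume (cm^3), > 0.
#' @param vol_treated treated tumor volume (cm^3), >= 0.
#' @return Efficacy in percent (vectorized).
#' @export
efficacy <- function(vol_control, vol_treated) {
  if (any(vol_control <= 0)) stop("vol_control must be positive", call. = FALSE)
  if (any(vol_treated < 0)) stop("vol_treated must be nonnegative", call. = FALSE)
  (vol_control - vol_treated) / vol_control * 100
}

#' Run one treatment scenario
#'
#' Simulates the free-boundary model from day 0 to the preset horizon, with
#' dosing on `[t0, horizon]`. All arms share the identical initial state, so
#' the resulting curves are directly comparable.
#'
#' @param preset a [scenario_preset()] (or name of one).
#' @param arm treatment arm: `"control"`, `"antiPD1"`, `"antiTGFb"`,
#'   `"combination"`.
#' @param p `kinetic_params`; the preset's cancer-specific pair overrides
#'   `zeta_Tb` and `lambda_T1Tr`.
#' @param cfg a [solver_config()].
#' @param gamma_A1,gamma_Ab dose rates (g/(cm^3*d)).
#' @return A `trajectory` with attributes `final_volume` (cm^3), `arm`,
#'   `preset`.
#' @export
run_scenario <- function(preset, arm = "control", p = default_params(),
                         cfg = solver_config(), gamma_A1 = 1e-8, gamma_Ab = 2e-6) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  stopifnot(inherits(preset, "scenario_preset"))
  p$zeta_Tb <- preset$zeta_Tb
  p$lambda_T1Tr <- preset$lambda_T1Tr
  p <- validate_params(p)
  sch <- treatment_schedule(arm, t0 = preset$t0, t1 = preset$horizon,
                            gamma_A1 = gamma_A1, gamma_Ab = gamma_Ab)
  init <- initial_state(p, N = cfg$N)
  traj <- simulate_tumor(init, p, sch, cfg, t_end = preset$horizon)
  attr(traj, "final_volume") <- traj$volume_cm3[nrow(traj)]
  attr(traj, "arm") <- arm
  attr(traj, "preset") <- preset$cancer
  traj
}

.sweep_preset <- function(zeta, lambda, t0, horizon) {
  structure(list(cancer = "custom", lambda_T1Tr = lambda, zeta_Tb = zeta,
                 t0 = t0, horizon = horizon), class = "scenario_preset")
}

#' Hyperprogression map over the two cancer-specific parameters
#'
#' Efficacy of anti-PD-1 monotherapy versus control at the final day, for
#' every pair on a grid of the TGF-beta killing-inhibition strength `zeta_Tb`
#' and the Th1->Treg conversion scale `lambda_T1Tr`. Each cell is an
#' independent pair of simulations (control depends on the pair too).
#'
#' @param zeta_grid,lambda_grid grid values (cm^3/g and 1/d).
#' @param p `kinetic_params`.
#' @param cfg a [solver_config()].
#' @param t0 treatment start (days); `horizon` final day.
#' @param gamma_A1 anti-PD-1 dose rate.
#' @return An `efficacy_map`: list with `axis1` (zeta), `axis2` (lambda),
#'   `efficacy` (matrix, rows = zeta, cols = lambda), `failures`, `meta`.
#' @export
hyperprogression_map <- function(zeta_grid = seq(0, 1.5e6, length.out = 6),
                                 lambda_grid = seq(0, 5e4, length.out = 6),
                                 p = default_params(), cfg = solver_config(),
                                 t0 = 15, horizon = 45, gamma_A1 = 1e-8) {
  eff <- matrix(NA_real_, length(zeta_grid), length(lambda_grid))
  fails <- list()
  for (i in seq_along(zeta_grid)) for (j in seq_along(lambda_grid)) {
    pr <- .sweep_preset(zeta_grid[i], lambda_grid[j], t0, horizon)
    cell <- tryCatch({
      vc <- attr(run_scenario(pr, "control", p, cfg), "final_volume")
      vt <- attr(run_scenario(pr, "antiPD1", p, cfg, gamma_A1 = gamma_A1),
                 "final_volume")
      efficacy(vc, vt)
    }, error = function(e) {
      fails[[length(fails) + 1]] <<- list(i = i, j = j, message = conditionMessage(e))
      NA_real_
    })
    eff[i, j] <- cell
  }
  structure(list(axis1 = zeta_grid, axis2 = lambda_grid, efficacy = eff,
                 failures = fails,
                 meta = list(kind = "hyperprogression", t0 = t0,
                             horizon = horizon, gamma_A1 = gamma_A1,
                             axis1_name = "zeta_Tb", axis2_name = "lambda_T1Tr")),
            class = "efficacy_map")
}

#' Dose-plane efficacy map for combination therapy
#'
#' Efficacy of the anti-PD-1 + anti-TGF-beta combination at the final day
#' over a grid of the two dose rates, for fixed cancer-specific parameters.
#'
#' @param gamma_Ab_grid,gamma_A1_grid dose grids (g/(cm^3*d)).
#' @param zeta_Tb,lambda_T1Tr cancer-specific parameters of the scenario.
#' @param p `kinetic_params`.
#' @param cfg a [solver_config()].
#' @param t0,horizon treatment start and final day (days).
#' @return An `efficacy_map` with `axis1` = gamma_Ab (rows), `axis2` =
#'   gamma_A1 (columns).
#' @export
efficacy_dose_map <- function(gamma_Ab_grid = seq(0, 2e-6, length.out = 5),
                              gamma_A1_grid = seq(0, 1e-8, length.out = 5),
                              zeta_Tb = 4e5, lambda_T1Tr = 6,
                              p = default_params(), cfg = solver_config(),
                              t0 = 14, horizon = 45) {
  pr <- .sweep_preset(zeta_Tb, lambda_T1Tr, t0, horizon)
  vc <- attr(run_scenario(pr, "control", p, cfg), "final_volume")
  eff <- matrix(NA_real_, length(gamma_Ab_grid), length(gamma_A1_grid))
  fails <- list()
  for (i in seq_along(gamma_Ab_grid)) for (j in seq_along(gamma_A1_grid)) {
    eff[i, j] <- tryCatch({
      vt <- attr(run_scenario(pr, "combination", p, cfg,
                              gamma_A1 = gamma_A1_grid[j],
                              gamma_Ab = gamma_Ab_grid[i]), "final_volume")
      efficacy(vc, vt)
    }, error = function(e) {
      fails[[length(fails) + 1]] <<- list(i = i, j = j, message = conditionMessage(e))
      NA_real_
    })
  }
  structure(list(axis1 = gamma_Ab_grid, axis2 = gamma_A1_grid, efficacy = eff,
                 failures = fails,
                 meta = list(kind = "dose", zeta_Tb = zeta_Tb,
                             lambda_T1Tr = lambda_T1Tr, t0 = t0, horizon = horizon,
                             axis1_name = "gamma_Ab", axis2_name = "gamma_A1")),
            class = "efficacy_map")
}

#' Tumor-averaged Treg density across the four treatment arms
#'
#' @param preset a [scenario_preset()] or its name (default gastric, where the
#'   Treg comparison is reported).
#' @param p `kinetic_params`.
#' @param cfg a [solver_config()].
#' @param day measurement day; defaults to the preset's final day.
#' @return Named numeric vector of tumor-averaged Treg densities (g/cm^3) for
#'   control, antiPD1, antiTGFb and combination.
#' @export
treg_comparison <- function(preset = "gastric", p = default_params(),
                            cfg = solver_config(), day = NULL) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  if (is.null(day)) day <- preset$horizon
  arms <- c("control", "antiPD1", "antiTGFb", "combination")
  out <- vapply(arms, function(a) {
    tr <- run_scenario(preset, a, p, cfg)
    i <- which.min(abs(tr$t_days - day))
    tr$Tr_avg_g_per_cm3[i]
  }, 0.0)
  names(out) <- arms
  out
}

#' Zero-efficacy boundary of a parameter map
#'
#' For each column of the first axis, the second-axis value at which the
#' efficacy crosses zero (linear interpolation between the bracketing grid
#' cells). For the hyperprogression map this is the curve
#' `lambda_T1Tr = f(zeta_Tb)` separating positive from negative efficacy.
#'
#' @param map an `efficacy_map` (rows = axis1, columns = axis2).
#' @return Data.frame with `axis1` and the interpolated crossing `boundary`
#'   (`NA` where the row does not change sign). Rows with more than one sign
#'   change raise an error naming the ambiguous axis value.
#' @export
sign_boundary <- function(map) {
  stopifnot(inherits(map, "efficacy_map"))
  eff <- map$efficacy
  out <- data.frame(axis1 = map$axis1, boundary = NA_real_)
  for (i in seq_along(map$axis1)) {
    row <- eff[i, ]
    sgn <- sign(row)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(flips) > 1)
      stop("ambiguous sign boundary: multiple sign changes at axis1 = ",
           map$axis1[i], call. = FALSE)
    if (length(flips) == 1) {
      k <- flips
      x0 <- map$axis2[k]; x1 <- map$axis2[k + 1]
      y0 <- row[k]; y1 <- row[k + 1]
      out$boundary[i] <- x0 - y0 * (x1 - x0) / (y1 - y0)
    } else if (all(sgn <= 0, na.rm = TRUE)) {
      out$boundary[i] <- map$axis2[1]
    }
  }
  if (all(eff >= 0, na.rm = TRUE)) out$boundary[] <- NA_real_
  out
}

#' @export
print.efficacy_map <- function(x, ...) {
  cat("Efficacy map (", x$meta$kind, "), ", length(x$axis1), " x ",
      length(x$axis2), " grid\n", sep = "")
  m <- round(x$efficacy, 2)
  dimnames(m) <- list(signif(x$axis1, 3), signif(x$axis2, 3))
  print(m)
  if (length(x$failures)) cat(length(x$failures), "cell(s) failed\n")
  invisible(x)
}
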