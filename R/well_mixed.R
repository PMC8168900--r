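# Spatially homogeneous reduction: all fields uniform, chemotaxis and
# diffusion vanish, and the velocity closure collapses to uniform dilation at
# rate g = (sum of cell reaction rates)/theta. Cell derivatives are taken in
# the dilating frame (dX = F_X - X*g) so the cell-sum constraint is preserved
# exactly; molecules do not advect and carry no dilution term. This is the
# exact uniform limit of the PDE with zero-flux boundaries, which makes the
# reduction a valid oracle for the radial solver.

#' Well-mixed time derivatives
#'
#' @param s named numeric vector: the 16 species (g/cm^3) plus `R` (cm).
#' @param p `kinetic_params`.
#' @param schedule a [treatment_schedule()].
#' @param t time (days), used for the dosing window.
#' @return Named vector of derivatives, same layout as `s`;
#'   `dR/dt = R * g / 3`.
#' @export
rhs_well_mixed <- function(s, p, schedule, t = 0) {
  cells <- as.list(s[.cell_species])
  mols <- as.list(s[.mol_species])
  fc <- cell_rhs(cells, mols, p)
  fm <- molecular_rhs(cells, mols, p, dose_rate(t, schedule))
  g <- sum(unlist(fc)) / p$theta
  d <- c(unlist(fc) - unlist(cells) * g, unlist(fm), R = unname(s[["R"]]) * g / 3)
  names(d) <- c(.all_species, "R")
  d
}

#' Integrate the well-mixed reduction
#'
#' Stiff integration (deSolve, `lsoda`) of [rhs_well_mixed()]. Output matches
#' the trajectory format of [simulate_tumor()].
#'
#' @param initial named vector of the 16 species plus `R`, or a `tumor_state`
#'   with uniform profiles.
#' @param p `kinetic_params`.
#' @param schedule a [treatment_schedule()].
#' @param t_end final time (days).
#' @param t0 start time (days).
#' @param cadence recording interval (days).
#' @param rtol,atol integrator tolerances.
#' @return A `trajectory` data.frame (`t_days`, `R_cm`, `volume_cm3`,
#'   species averages). Attribute `final_values`: named state vector at `t_end`.
#' @export
simulate_ode <- function(initial, p, schedule, t_end, t0 = 0, cadence = 1,
                         rtol = 1e-8, atol = 1e-16) {
  if (inherits(initial, "tumor_state")) {
    y0 <- c(colMeans(initial$state), R = initial$R)
    t0 <- initial$t
  } else y0 <- initial[c(.all_species, "R")]
  if (t_end <= t0) stop("t_end must exceed t0", call. = FALSE)
  times <- unique(c(seq(t0, t_end, by = cadence), t_end))
  # event times at the dosing window edges keep lsoda from stepping across them
  sw <- c(schedule$t0, schedule$t1)
  sw <- sort(unique(sw[sw > t0 & sw < t_end]))
  ev <- if (length(sw)) list(func = function(t, y, parms) y, time = sw) else NULL
  out <- deSolve::lsoda(
    y = y0, times = times,
    func = function(t, y, parms) {
      y[y < 0] <- 0
      list(rhs_well_mixed(y, p, schedule, t))
    },
    parms = NULL, rtol = rtol, atol = atol, maxsteps = 50000,
    events = ev
  )
  if (attr(out, "istate")[1] < 0)
    stop("well-mixed integrator failure; final state: ",
         paste(sprintf("%s=%.3e", colnames(out), out[nrow(out), ]), collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(out)
  traj <- data.frame(t_days = df$time, R_cm = df$R,
                     volume_cm3 = tumor_volume(df$R))
  avg <- as.matrix(df[, .all_species])
  colnames(avg) <- paste0(.all_species, "_avg_g_per_cm3")
  traj <- cbind(traj, as.data.frame(avg))
  fin <- unlist(df[nrow(df), c(.all_species, "R")])
  attr(traj, "final_values") <- fin
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Drug-free uniform steady state
#'
#' Finds a root of the well-mixed reaction system (excluding `R`; cell
#' derivatives in the dilating frame) by integrating from the documented
#' uniform start until near-stationary and polishing with damped Newton
#' iterations on a finite-difference Jacobian.
#'
#' @param p drug-free `kinetic_params`.
#' @param burn_in integration time used to approach the root (days).
#' @param tol residual norm tolerance, relative to `theta`.
#' @param max_iter Newton iteration budget.
#' @param start optional named 16-vector starting point.
#' @return List with `state` (named 16-vector), `residual` (norm), `g`
#'   (dilation rate at the root, 1/d).
#' @export
solve_steady_state <- function(p, burn_in = 400, tol = 1e-10, max_iter = 50,
                               start = NULL) {
  sch <- treatment_schedule("control", t0 = 0, t1 = 0)
  if (is.null(start)) start <- uniform_initial_values(p, init = "fractions")
  tr <- simulate_ode(c(start, R = 0.1), p, sch, t_end = burn_in, cadence = burn_in)
  y <- attr(tr, "final_values")[.all_species]
  fn <- function(v) {
    v[v < 0] <- 0
    rhs_well_mixed(c(v, R = 1), p, sch, t = 0)[.all_species]
  }
  scale <- pmax(abs(y), 1e-14)
  for (it in seq_len(max_iter)) {
    r <- fn(y)
    if (sqrt(sum(r^2)) < tol * p$theta) break
    J <- matrix(0, 16, 16)
    for (k in 1:16) {
      hk <- 1e-7 * scale[k]
      yk <- y; yk[k] <- yk[k] + hk
      J[, k] <- (fn(yk) - r) / hk
    }
    dy <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dy)) break
    lam <- 1
    repeat {
      y2 <- pmax(y + lam * dy, 0)
      if (sqrt(sum(fn(y2)^2)) < sqrt(sum(r^2)) || lam < 1e-4) break
      lam <- lam / 2
    }
    y <- pmax(y + lam * dy, 0)
  }
  r <- fn(y)
  resid <- sqrt(sum(r^2))
  if (resid >= tol * p$theta)
    stop(sprintf(
      "steady-state solve did not converge: residual %.3e (tolerance %.3e)",
      resid, tol * p$theta), call. = FALSE)
  g <- sum(unlist(cell_rhs(as.list(y[.cell_species]), as.list(y[.mol_species]), p))) / p$theta
  list(state = y, residual = resid, g = g)
}
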