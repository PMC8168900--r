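#' Write a trajectory to CSV
#'
#' Header: `t_days,R_cm,volume_cm3,<species>_avg_g_per_cm3...`. Optionally a
#' long-format radial snapshot of the final state (`t, rho, species, value`).
#'
#' @param traj a `trajectory` (from [simulate_tumor()] or [simulate_ode()]).
#' @param path output CSV path.
#' @param snapshot_path optional path for the long-format final radial snapshot
#'   (only available for PDE trajectories).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, snapshot_path = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  if (!is.null(snapshot_path)) {
    fs <- attr(traj, "final_state")
    if (is.null(fs)) stop("trajectory carries no radial snapshot", call. = FALSE)
    long <- data.frame(
      t = fs$t,
      rho = rep(fs$rho, times = ncol(fs$state)),
      species = rep(colnames(fs$state), each = nrow(fs$state)),
      value = as.vector(fs$state)
    )
    utils::write.csv(long, snapshot_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write an efficacy map to JSON (and optionally CSV)
#'
#' JSON carries the axes, the matrix and the metadata; the companion CSV is
#' long format (`axis1, axis2, efficacy_pct`).
#'
#' @param map an `efficacy_map`.
#' @param path output JSON path.
#' @param csv_path optional companion CSV path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, csv_path = NULL) {
  stopifnot(inherits(map, "efficacy_map"))
  jsonlite::write_json(
    list(axis1 = map$axis1, axis2 = map$axis2, efficacy = map$efficacy,
         meta = map$meta),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  if (!is.null(csv_path)) {
    long <- expand.grid(axis1 = map$axis1, axis2 = map$axis2)
    long$efficacy_pct <- as.vector(map$efficacy)
    utils::write.csv(long, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Load a run configuration
#'
#' Reads a parameter file (see [load_params()]) plus an optional preset name
#' or inline overrides, returning the validated pieces a run needs.
#'
#' @param params_file path to a YAML parameter file, or `NULL` for the shipped
#'   defaults.
#' @param preset preset name (see [scenario_preset()]) or `NULL`.
#' @param overrides named list of parameter overrides (known symbols only).
#' @param N,dt solver settings.
#' @return List with elements `params`, `preset`, `config`.
#' @export
load_config <- function(params_file = NULL, preset = NULL, overrides = list(),
                        N = 65, dt = 1e-3) {
  p <- if (is.null(params_file)) {
    load_params(system.file("extdata", "params_default.yaml", package = "tumorpde"))
  } else load_params(params_file)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), .param_names())
    if (length(unknown))
      stop("unknown override symbol(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(overrides)] <- overrides
    p <- validate_params(p)
  }
  pr <- if (is.null(preset)) NULL else scenario_preset(preset)
  list(params = p, preset = pr, config = solver_config(N = N, dt = dt))
}

#' Reproducible fixtures for tests and examples
#'
#' * `uniform-state`: the default uniform initial state.
#' * `random-state`: a seeded random admissible state (cells rescaled to sum
#'   to `theta`, molecules log-uniform around their default balance).
#' * `logistic-only-params`: every rate zero except cancer growth and death
#'   (the closed-form exponential-growth configuration).
#' * `frozen-params`: all rates zero (nothing moves).
#'
#' @param kind fixture kind.
#' @param seed RNG seed for `random-state`.
#' @param p base parameters.
#' @param N mesh nodes for state fixtures.
#' @return A `tumor_state` or `kinetic_params`, per `kind`.
#' @export
make_fixture <- function(kind = c("uniform-state", "random-state",
                                  "logistic-only-params", "frozen-params"),
                         seed = 1, p = default_params(), N = 33) {
  kind <- match.arg(kind)
  rates <- setdiff(grep("^lambda_|^mu_", .param_names(), value = TRUE), character())
  switch(kind,
    "uniform-state" = initial_state(p, N = N),
    "random-state" = {
      set.seed(seed)
      cells <- stats::runif(7, 0.01, 1)
      cells <- cells / sum(cells) * p$theta
      names(cells) <- .cell_species
      base <- uniform_initial_values(p)[.mol_species]
      mols <- base * stats::runif(9, 0.2, 5)
      mols[c("A1", "Ab")] <- abs(stats::rnorm(2, 0, 1e-8))
      prof <- c(as.list(cells), as.list(mols))
      # mild radial modulation, cells re-projected to the constraint
      m <- .state_matrix(prof, N)
      rho <- seq(0, 1, length.out = N)
      for (s in .mol_species) m[, s] <- m[, s] * (1 + 0.3 * stats::runif(1, -1, 1) * rho^2)
      for (s in .cell_species) m[, s] <- m[, s] * (1 + 0.3 * stats::runif(1, -1, 1) * rho^2)
      m[, .cell_species] <- m[, .cell_species] * p$theta /
        rowSums(m[, .cell_species])
      tumor_state(m, R = stats::runif(1, 0.05, 0.5), t = 0, p = p)
    },
    "logistic-only-params" = {
      q <- p
      for (k in rates) q[[k]] <- 0
      q$lambda_C <- p$lambda_C
      q$mu_C <- p$mu_C
      validate_params(q)
    },
    "frozen-params" = {
      q <- p
      for (k in rates) q[[k]] <- 0
      validate_params(q)
    })
}
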