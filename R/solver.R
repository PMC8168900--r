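#' Solver configuration
#'
#' @param N number of mesh nodes on the normalized radius `rho in [0,1]`
#'   (default 65).
#' @param dt time step (days). The scheme is IMEX: implicit in diffusion and
#'   the linear degradation/blocking losses of the molecular species, explicit
#'   in reactions, advection and chemotaxis. Steps violating the advective CFL
#'   bound are rejected and halved.
#' @param cadence output recording interval (days).
#' @param cfl CFL safety factor for the explicit advection terms.
#' @return A `solver_config` object.
#' @export
solver_config <- function(N = 65, dt = 1e-3, cadence = 1, cfl = 0.5) {
  if (N < 3) stop("N must be at least 3", call. = FALSE)
  if (dt < 0) stop("dt must be nonnegative", call. = FALSE)
  if (cadence <= 0) stop("cadence must be positive", call. = FALSE)
  structure(list(N = as.integer(N), dt = dt, cadence = cadence, cfl = cfl),
            class = "solver_config")
}

# Column order of profile matrices everywhere in the package.
.state_matrix <- function(profiles, N) {
  m <- matrix(0, N, length(.all_species), dimnames = list(NULL, .all_species))
  for (s in names(profiles)) m[, s] <- profiles[[s]]
  m
}

#' Tumor state on the normalized radial mesh
#'
#' Bundles the per-species radial profiles (rows = mesh nodes, columns =
#' species), the boundary radius, and the clock. Profiles are stored on the
#' front-fixed mesh `rho = r/R(t)`, `rho_j` uniform in `[0, 1]`.
#'
#' @param profiles named list of per-species profiles (scalar values are
#'   recycled to the mesh), or a full `N x 16` matrix with species columns.
#' @param R boundary radius (cm), > 0.
#' @param t clock (days).
#' @param N mesh nodes (ignored if `profiles` is a matrix).
#' @param p `kinetic_params`, used to check the cell-sum invariant.
#' @param check if `TRUE`, verify nonnegativity and the cell-sum constraint.
#' @return A `tumor_state` object with elements `state` (matrix), `rho`, `R`, `t`.
#' @export
tumor_state <- function(profiles, R = 0.1, t = 0, N = 65, p = NULL, check = TRUE) {
  if (is.matrix(profiles)) {
    m <- profiles
    if (!identical(colnames(m), .all_species))
      stop("profile matrix must have the 16 species columns in canonical order",
           call. = FALSE)
    N <- nrow(m)
  } else {
    m <- .state_matrix(profiles, N)
  }
  if (R <= 0) stop("boundary radius R must be positive", call. = FALSE)
  if (check) {
    if (any(m < 0)) stop("negative species profile", call. = FALSE)
    if (!is.null(p)) {
      dev <- max(abs(rowSums(m[, .cell_species]) - p$theta))
      if (dev > 1e-6 * p$theta)
        stop(sprintf("cell profiles do not sum to theta (max deviation %.3e)", dev),
             call. = FALSE)
    }
  }
  structure(list(state = m, rho = seq(0, 1, length.out = N), R = R, t = t),
            class = "tumor_state")
}

#' Uniform initial tumor state
#'
#' Default initialisation: a small spheroid (`R = 0.1` cm) with uniform
#' profiles. Cancer occupies a fixed fraction of the total cell density and
#' the immune species share the remainder in fixed proportions; molecular
#' species start at their production/degradation balance given those cells
#' (drug-free). With `init = "steady"` the uniform drug-free steady state of
#' the well-mixed reduction is used instead.
#'
#' @param p `kinetic_params`.
#' @param N mesh nodes.
#' @param R0 initial radius (cm).
#' @param cancer_fraction fraction of `theta` occupied by cancer cells.
#' @param init `"fractions"` (default) or `"steady"`.
#' @return A `tumor_state`.
#' @export
initial_state <- function(p, N = 65, R0 = 0.1, cancer_fraction = 0.8,
                          init = c("fractions", "steady")) {
  init <- match.arg(init)
  u <- uniform_initial_values(p, cancer_fraction = cancer_fraction, init = init)
  tumor_state(as.list(u), R = R0, t = 0, N = N, p = p)
}

#' @rdname initial_state
#' @return `uniform_initial_values()`: a named vector of the 16 species values.
#' @export
uniform_initial_values <- function(p, cancer_fraction = 0.8,
                                   init = c("fractions", "steady")) {
  init <- match.arg(init)
  if (init == "steady") {
    ss <- solve_steady_state(p)
    return(ss$state)
  }
  if (cancer_fraction <= 0 || cancer_fraction >= 1)
    stop("cancer_fraction must be in (0, 1)", call. = FALSE)
  # immune split of the non-cancer share, fixed documented proportions
  imm <- c(M1 = 0.2, M2 = 0.6, D = 0.04, T1 = 0.06, T8 = 0.05, Tr = 0.05)
  cells <- c(C = cancer_fraction, imm * (1 - cancer_fraction)) * p$theta
  mols <- c(
    I2  = p$lambda_I2T1 * cells[["T1"]] / p$mu_I2,
    I10 = (p$lambda_I10M2 * cells[["M2"]] + p$lambda_I10C * cells[["C"]]) / p$mu_I10,
    I12 = p$lambda_I12D * cells[["D"]] / p$mu_I12,
    P   = p$lambda_PC * cells[["C"]] / p$mu_P,
    Tb  = (p$lambda_TbC * cells[["C"]] + p$lambda_TbM2 * cells[["M2"]] +
             p$lambda_TbTr * cells[["Tr"]]) / p$mu_Tb,
    PD  = p$lambda_PD * sum(cells[c("T1", "T8", "Tr")]) / p$mu_PD,
    PL  = (p$lambda_PL1 * sum(cells[c("T1", "T8", "Tr", "M1", "M2")]) +
             p$lambda_PLC * cells[["C"]]) / p$mu_PL,
    A1 = 0, Ab = 0
  )
  c(cells, mols)[.all_species]
}

.params_vector <- function(p) {
  v <- unlist(unclass(validate_params(p)))
  v[.param_names()]
}

#' Radial velocity from the constant-density closure
#'
#' Summing the seven cell equations under the constraint that the combined
#' cell density stays equal to `theta` leaves a divergence equation for the
#' radial velocity: `theta * (1/r^2) d(r^2 u)/dr` equals the total cell
#' source (reactions + diffusion + chemotaxis). `u` is obtained by cumulative
#' quadrature of `r^2 * source / theta` with `u(0) = 0`.
#'
#' @param ts a `tumor_state`.
#' @param p `kinetic_params`.
#' @param dose length-2 numeric drug source rates (g/(cm^3*d)).
#' @param tol relative tolerance for the cell-sum precondition.
#' @return Numeric vector: the velocity profile `u(rho)` in cm/d.
#' @export
compute_velocity <- function(ts, p, dose = c(0, 0), tol = 1e-6) {
  stopifnot(inherits(ts, "tumor_state"))
  dev <- max(abs(rowSums(ts$state[, .cell_species]) - p$theta))
  if (dev > tol * p$theta) {
    j <- which.max(abs(rowSums(ts$state[, .cell_species]) - p$theta))
    stop(sprintf(
      "cell-sum constraint violated: max deviation %.3e at node %d", dev, j),
      call. = FALSE)
  }
  cpp_velocity(ts$state, ts$R, .params_vector(p), as.numeric(dose))$u
}

#' Advance the free boundary
#'
#' `dR/dt = u(R, t)`: one explicit Euler update of the boundary radius,
#' matching the order of the field step.
#'
#' @param R boundary radius (cm), > 0.
#' @param u_R velocity at the boundary (cm/d).
#' @param dt time step (days).
#' @return The updated radius. A nonpositive result signals collapse
#'   (tumor elimination) as a condition `"tumor_collapse"`.
#' @export
advance_boundary <- function(R, u_R, dt) {
  if (R <= 0) stop("R must be positive", call. = FALSE)
  R2 <- R + dt * u_R
  if (R2 <= 0)
    stop(structure(class = c("tumor_collapse", "error", "condition"),
                   list(message = "boundary collapsed: tumor eliminated",
                        call = sys.call())))
  R2
}

#' One time step of the full free-boundary system
#'
#' @param ts a `tumor_state`.
#' @param p `kinetic_params`.
#' @param schedule a [treatment_schedule()].
#' @param cfg a [solver_config()]; `cfg$dt` is the step taken.
#' @return The updated `tumor_state` (with attributes `max_constraint_dev`
#'   and `max_projection`). A zero step returns the state unchanged.
#' @export
step_tumor <- function(ts, p, schedule, cfg = solver_config()) {
  stopifnot(inherits(ts, "tumor_state"))
  if (cfg$dt == 0) return(ts)
  res <- cpp_simulate(ts$state, ts$R, ts$t, ts$t + cfg$dt,
                      .params_vector(p), unclass(schedule),
                      list(dt = cfg$dt, cadence = cfg$dt, cfl = cfg$cfl))
  out <- tumor_state(`colnames<-`(res$state, .all_species),
                     R = res$R_final, t = res$t_final, p = NULL, check = FALSE)
  attr(out, "max_constraint_dev") <- res$max_constraint_dev
  attr(out, "max_projection") <- res$max_projection
  out
}

#' Simulate the free-boundary model
#'
#' Integrates the full radially symmetric system from `initial$t` to `t_end`,
#' recording the boundary radius, tumor volume and tumor-averaged species
#' densities at the output cadence. Deterministic: identical inputs give
#' identical outputs.
#'
#' @param initial a `tumor_state` (see [initial_state()]).
#' @param p `kinetic_params`.
#' @param schedule a [treatment_schedule()].
#' @param cfg a [solver_config()].
#' @param t_end final time (days), greater than `initial$t`.
#' @return A `trajectory`: data.frame with columns `t_days`, `R_cm`,
#'   `volume_cm3` and one `<species>_avg_g_per_cm3` column per species.
#'   Attributes: `final_state` (a `tumor_state`), `max_constraint_dev`,
#'   `max_projection`, `collapsed`.
#' @export
simulate_tumor <- function(initial, p, schedule, cfg = solver_config(), t_end) {
  stopifnot(inherits(initial, "tumor_state"))
  if (t_end <= initial$t) stop("t_end must exceed the initial clock", call. = FALSE)
  res <- cpp_simulate(initial$state, initial$R, initial$t, t_end,
                      .params_vector(p), unclass(schedule),
                      list(dt = cfg$dt, cadence = cfg$cadence, cfl = cfg$cfl))
  traj <- data.frame(t_days = res$time, R_cm = res$R,
                     volume_cm3 = tumor_volume(res$R))
  avg <- res$avg
  colnames(avg) <- paste0(.all_species, "_avg_g_per_cm3")
  traj <- cbind(traj, as.data.frame(avg))
  attr(traj, "final_state") <- tumor_state(`colnames<-`(res$state, .all_species),
                                           R = res$R_final, t = res$t_final,
                                           check = FALSE)
  attr(traj, "max_constraint_dev") <- res$max_constraint_dev
  attr(traj, "max_projection") <- res$max_projection
  attr(traj, "collapsed") <- res$collapsed
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Spherical tumor volume
#'
#' @param R boundary radius (cm), >= 0 (vectorized).
#' @return `(4/3) * pi * R^3` (cm^3).
#' @export
tumor_volume <- function(R) {
  if (any(R < 0)) stop("R must be nonnegative", call. = FALSE)
  4 / 3 * pi * R^3
}

#' Volume-weighted radial average
#'
#' `3 * int_0^1 rho^2 X(rho) drho`: the mean of a profile over the spherical
#' tumor. The profile is taken piecewise linear between nodes and the `rho^2`
#' moment of each panel is integrated exactly, so constant and linear profiles
#' average without quadrature bias.
#'
#' @param profile values on the normalized mesh.
#' @param mesh normalized radii (defaults to a uniform mesh).
#' @return Scalar average (same units as `profile`).
#' @export
radial_average <- function(profile, mesh = seq(0, 1, length.out = length(profile))) {
  if (length(profile) != length(mesh)) stop("profile/mesh length mismatch", call. = FALSE)
  s0 <- head(mesh, -1); s1 <- tail(mesh, -1)
  x0 <- head(profile, -1); x1 <- tail(profile, -1)
  i3 <- (s1^3 - s0^3) / 3
  i4 <- (s1^4 - s0^4) / 4
  slope <- ifelse(s1 > s0, (x1 - x0) / (s1 - s0), 0)
  3 * sum(x0 * i3 + slope * (i4 - s0 * i3))
}

#' @importFrom utils head tail
NULL
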