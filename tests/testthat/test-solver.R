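test_that("velocity closure: frozen system is motionless, uniform production gives u = g r / 3", {
  pf <- make_fixture("frozen-params")
  N <- 33
  ts <- initial_state(default_params(), N = N)
  u0 <- compute_velocity(ts, pf)
  expect_equal(u0, rep(0, N), tolerance = 1e-18)
  # uniform state with real reactions: sources are uniform, u is linear in rho
  p <- default_params()
  u <- compute_velocity(ts, p)
  S <- tumorpde:::cpp_velocity(ts$state, ts$R, tumorpde:::.params_vector(p),
                               c(0, 0))$S
  expect_lt(diff(range(S)), 1e-12 * max(abs(S)))  # uniform source
  g <- S[1] / p$theta
  expect_equal(u, g * ts$rho * ts$R / 3, tolerance = 1e-12)
})

test_that("velocity quadrature matches the analytic antiderivative for an r^2 source", {
  # S(rho) = a * rho^2  =>  u = R a rho^3 / (5 theta)
  p <- default_params()
  N <- 65; R <- 0.2; a <- 0.05
  rho <- seq(0, 1, length.out = N)
  S <- a * rho^2
  u_pkg <- tumorpde:::cpp_velocity_quadrature(S, R, p$theta)
  u_exact <- R * a * rho^3 / (5 * p$theta)
  h <- 1 / (N - 1)
  expect_lt(max(abs(u_pkg - u_exact)), 5 * h^2 * max(abs(u_exact)))
})

test_that("boundary advance: stationary, shrinking and exponential growth", {
  expect_equal(advance_boundary(0.2, 0, 0.01), 0.2)
  expect_lt(advance_boundary(0.2, -0.5, 0.01), 0.2)
  expect_error(advance_boundary(0.2, -100, 0.01), "collapsed")
  expect_error(advance_boundary(0, 0, 0.01), "positive")
  # constant relative growth u_R = g R / 3 integrates to an exponential
  g <- 0.05; R <- 0.1; dt <- 1e-3
  for (i in seq_len(1000)) R <- advance_boundary(R, g * R / 3, dt)
  expect_equal(R, 0.1 * exp(g * 1 / 3), tolerance = 1e-4)
})

test_that("uniform states stay uniform and a zero step is the identity", {
  p <- default_params()
  cfg <- test_cfg()
  ts <- initial_state(p, N = cfg$N)
  sch <- treatment_schedule("combination", 0, 10)
  s1 <- step_tumor(ts, p, sch, cfg)
  for (s in colnames(s1$state)) {
    rng <- diff(range(s1$state[, s]))
    expect_lt(rng, 1e-10 * max(s1$state[, s], 1e-300))
  }
  expect_gt(s1$R, ts$R)
  s0 <- step_tumor(ts, p, sch, solver_config(N = cfg$N, dt = 0))
  expect_identical(s0$state, ts$state)
  expect_identical(s0$R, ts$R)
})

test_that("cancer-only tumor grows exponentially at rate g/3 (0.1% closed form)", {
  p <- make_fixture("logistic-only-params")
  N <- 33
  ts <- tumor_state(list(C = p$theta), R = 0.1, N = N, p = p)
  tr <- simulate_tumor(ts, p, treatment_schedule("control", 0, 0),
                       test_cfg(), t_end = 45)
  g <- p$lambda_C * (1 - p$theta / p$C_M) - p$mu_C
  expect_equal(tail(tr$R_cm, 1), 0.1 * exp(g * 45 / 3), tolerance = 1e-3)
  # day-45 volume against the closed form, within 0.1%
  expect_lt(abs(final_volume(tr) / tumor_volume(0.1 * exp(g * 45 / 3)) - 1), 1e-3)
})

test_that("constraint and positivity hold over 1000 steps; projection stays tiny", {
  p <- default_params(zeta_Tb = 4e6, lambda_T1Tr = 1e3)
  cfg <- solver_config(N = 33, dt = 1e-3)
  ts <- initial_state(p, N = 33)
  sch <- treatment_schedule("combination", 0, 2)
  tr <- simulate_tumor(ts, p, sch, cfg, t_end = 1)  # 1000 steps of 1e-3
  expect_lt(attr(tr, "max_constraint_dev"), 1e-6 * p$theta)
  expect_lt(attr(tr, "max_projection"), 1e-8 * p$theta)
  fs <- attr(tr, "final_state")
  expect_true(all(fs$state >= -1e-12 * p$theta))
  expect_lt(max(abs(rowSums(fs$state[, cell_species()]) - p$theta)), 1e-6 * p$theta)
})

test_that("symmetry: u(0) = 0 exactly and profiles are flat at the center", {
  p <- default_params()
  ts <- make_fixture("random-state", seed = 5, N = 33)
  u <- compute_velocity(ts, p)
  expect_identical(u[1], 0)
  sch <- treatment_schedule("control", 0, 0)
  s1 <- ts
  for (k in 1:50) s1 <- step_tumor(s1, p, sch, solver_config(N = 33, dt = 1e-3))
  grad0 <- abs(s1$state[2, ] - s1$state[1, ])
  scale <- pmax(apply(s1$state, 2, max), 1e-300)
  expect_lt(max(grad0 / scale), 0.05)  # zero-gradient center after smoothing
})

test_that("uniform-data PDE matches the well-mixed reduction to 1e-3 over 45 days", {
  p <- default_params(zeta_Tb = 4e6, lambda_T1Tr = 1e3)
  sch <- treatment_schedule("combination", 15, 45)
  tr_pde <- simulate_tumor(initial_state(p, N = 33), p, sch,
                           solver_config(N = 33, dt = 5e-4), t_end = 45)
  tr_ode <- simulate_ode(c(uniform_initial_values(p), R = 0.1), p, sch, t_end = 45)
  expect_equal(nrow(tr_pde), nrow(tr_ode))
  expect_lt(max(abs(tr_pde$R_cm / tr_ode$R_cm - 1)), 1e-3)
  # species comparison away from the switch-on day, where the fast TGF-beta
  # turnover and the antibody ramp make samples sensitive to event ordering
  keep <- tr_pde$t_days < 15 | tr_pde$t_days > 16
  for (s in c("C", "Tr", "T8", "Tb")) {
    a <- tr_pde[[paste0(s, "_avg_g_per_cm3")]][keep]
    b <- tr_ode[[paste0(s, "_avg_g_per_cm3")]][keep]
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-14)), 1e-3)
  }
})

test_that("grid and step refinement changes the day-45 volume by < 1%", {
  p <- default_params()  # colon-like defaults
  sch <- treatment_schedule("combination", 6, 45)
  v1 <- final_volume(simulate_tumor(initial_state(p, N = 33), p, sch,
                                    solver_config(N = 33, dt = 2e-3), t_end = 45))
  v2 <- final_volume(simulate_tumor(initial_state(p, N = 65), p, sch,
                                    solver_config(N = 65, dt = 1e-3), t_end = 45))
  expect_lt(abs(v1 / v2 - 1), 0.01)
})

test_that("antibody washes out at least as fast as its degradation rate after t1", {
  p <- default_params()
  sch <- treatment_schedule("antiPD1", t0 = 2, t1 = 10)
  tr <- simulate_tumor(initial_state(p, N = 17), p, sch,
                       solver_config(N = 17, dt = 2e-3), t_end = 30)
  a <- tr$A1_avg_g_per_cm3
  t <- tr$t_days
  post <- which(t >= 10.0)
  a1 <- a[post]; tp <- t[post]
  bound <- a1[1] * exp(-p$mu_A1 * (tp - tp[1]))
  expect_true(all(a1 <= bound * (1 + 1e-6)))
  expect_gt(a1[1], 0)
})

test_that("volume and radial averages have their closed forms", {
  expect_equal(tumor_volume(0), 0)
  expect_equal(tumor_volume(1), 4 * pi / 3)
  expect_equal(tumor_volume(2), 8 * tumor_volume(1))
  expect_error(tumor_volume(-1), "nonnegative")
  rho <- seq(0, 1, length.out = 201)
  expect_equal(radial_average(rep(3.2, 201), rho), 3.2, tolerance = 1e-12)
  expect_equal(radial_average(rho, rho), 3 / 4, tolerance = 1e-4)
  expect_equal(radial_average(rep(0, 201), rho), 0)
})

test_that("constraint-violating states are rejected with the deviating node named", {
  p <- default_params()
  ts <- initial_state(p, N = 17)
  ts$state[5, "C"] <- ts$state[5, "C"] * 1.5
  expect_error(compute_velocity(ts, p), "node")
  expect_error(tumor_state(ts$state, R = 0.1, p = p), "theta")
})
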