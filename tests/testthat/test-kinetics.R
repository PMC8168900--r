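test_that("saturation and inhibition fractions behave as defined", {
  K <- 3.7e-10
  expect_equal(mm_act(0, K), 0)
  expect_equal(mm_act(K, K), 0.5)
  expect_lt(abs(mm_act(1e6 * K, K) - 1), 1e-5)
  expect_equal(inhibit(0, K), 1)
  expect_equal(inhibit(K, K), 0.5)
  expect_lt(inhibit(1e6 * K, K), 1e-5)
  # duality on random inputs
  set.seed(3)
  x <- 10^runif(50, -12, -2)
  expect_equal(inhibit(x, K), 1 - mm_act(x, K), tolerance = 1e-14)
  # monotonicity
  xs <- sort(x)
  expect_true(all(diff(mm_act(xs, K)) >= 0))
  expect_true(all(diff(inhibit(xs, K)) <= 0))
  expect_error(mm_act(-1, K), "nonnegative")
  expect_error(mm_act(1, 0), "positive")
  expect_error(inhibit(-1, K), "nonnegative")
})

test_that("killing term has the stated limits and matches direct arithmetic", {
  expect_equal(killing_term(0.3, 2e-3, 1e-6, 17, 0), 17 * 2e-3 * 0.3)
  z <- 4e6
  expect_equal(killing_term(0.3, 2e-3, 1 / z, 17, z), 17 * 2e-3 * 0.3 / 2)
  # strictly decreasing in TGF-beta
  ks <- sapply(c(0, 1e-7, 1e-6, 1e-5), function(tb) killing_term(0.3, 2e-3, tb, 17, z))
  expect_true(all(diff(ks) < 0))
  # fixture state against an independently coded check
  C <- 0.41; T8 <- 1.3e-3; Tb <- 5.2e-6
  expect_equal(killing_term(C, T8, Tb, 17, z),
               (17 * T8) * C * (1 + z * Tb)^-1, tolerance = 1e-15)
  expect_error(killing_term(-0.1, T8, Tb, 17, z), "nonnegative")
})

test_that("complex formation is bilinear", {
  expect_equal(complex_Q(0, 5e-10, 1e10), 0)
  expect_equal(complex_Q(1e-10, 5e-10, 1), 5e-20)
  expect_equal(complex_Q(2e-10, 5e-10, 1e10), 2 * complex_Q(1e-10, 5e-10, 1e10))
  expect_error(complex_Q(-1e-10, 5e-10, 1e10), "nonnegative")
})

test_that("dose rates respect the window and the arm masks", {
  sch <- treatment_schedule("combination", t0 = 6, t1 = 45)
  expect_equal(unname(dose_rate(3, sch)), c(0, 0))
  expect_equal(unname(dose_rate(20, sch)), c(1e-8, 2e-6))
  expect_equal(unname(dose_rate(45, sch)), c(1e-8, 2e-6))  # inclusive end
  expect_equal(unname(dose_rate(45.01, sch)), c(0, 0))
  expect_equal(unname(dose_rate(20, treatment_schedule("antiPD1", 6, 45))),
               c(1e-8, 0))
  expect_equal(unname(dose_rate(20, treatment_schedule("antiTGFb", 6, 45))),
               c(0, 2e-6))
  expect_equal(unname(dose_rate(20, treatment_schedule("control", 6, 45))),
               c(0, 0))
  expect_error(treatment_schedule("combination", t0 = 10, t1 = 2), "t0 <= t1")
})

test_that("all-zero state is a fixed point of the reaction terms", {
  p <- default_params()
  y <- as.list(setNames(rep(0, 16), c(cell_species(), molecular_species())))
  f <- pkg_rhs(y, p)
  expect_equal(unname(f), rep(0, 16))
})

test_that("cancer at carrying capacity with no killers loses mass at mu_C", {
  p <- default_params()
  y <- as.list(setNames(rep(0, 16), c(cell_species(), molecular_species())))
  y$C <- p$C_M
  f <- pkg_rhs(y, p)
  expect_equal(unname(f["C"]), -p$mu_C * p$C_M, tolerance = 1e-14)
})

test_that("reaction evaluators match the independent oracle to 1e-12", {
  p <- default_params(zeta_Tb = 4e6, lambda_T1Tr = 1e3)
  states <- random_states(100)
  pv <- tumorpde:::.params_vector(p)
  for (y in states) {
    expected <- oracle_rhs(y, p, doseA1 = 1e-8, doseAb = 2e-6)
    got_r <- pkg_rhs(y, p, doseA1 = 1e-8, doseAb = 2e-6)
    got_c <- tumorpde:::cpp_react(unlist(y), pv, c(1e-8, 2e-6))
    scale <- pmax(abs(expected), 1e-300)
    expect_lt(max(abs(got_r - expected) / scale), 1e-12)
    expect_lt(max(abs(got_c - expected) / scale), 1e-12)
  }
})

test_that("conversion and phenotype-switch fluxes conserve cell mass", {
  p <- default_params()
  for (y in random_states(20, seed = 11)) {
    f1 <- pkg_rhs(y, p)
    p2 <- p; p2$lambda_T1Tr <- 1e4
    f2 <- pkg_rhs(y, p2)
    # the conversion term moves mass between T1 and Tr but their sum is untouched
    expect_equal(f1[["T1"]] + f1[["Tr"]], f2[["T1"]] + f2[["Tr"]], tolerance = 1e-12)
    p3 <- p; p3$lambda_M1M2 <- 0; p3$lambda_M2M1 <- 0
    f3 <- pkg_rhs(y, p3)
    expect_equal(f1[["M1"]] + f1[["M2"]], f3[["M1"]] + f3[["M2"]], tolerance = 1e-12)
  }
})

test_that("TGF-beta decays faster under the blocking antibody", {
  p <- default_params()
  y <- as.list(setNames(rep(0, 16), c(cell_species(), molecular_species())))
  y$Tb <- 1e-6; y$Ab <- 1e-5
  f <- pkg_rhs(y, p)
  expect_equal(f[["Tb"]], -(p$mu_Tb + p$mu_AbTb * y$Ab) * y$Tb, tolerance = 1e-14)
  y0 <- y; y0$Ab <- 0
  expect_lt(f[["Tb"]], pkg_rhs(y0, p)[["Tb"]])
})

test_that("parameter validation names the offending symbol", {
  expect_s3_class(default_params(), "kinetic_params")
  expect_error(default_params(theta = 0), "theta")
  expect_error(default_params(K_Q = 0), "K_Q")
  expect_error(default_params(mu_C = -1), "mu_C")
  expect_error(default_params(not_a_rate = 1), "not_a_rate")
  # the gastric pair is admissible
  expect_silent(default_params(zeta_Tb = 4e6, lambda_T1Tr = 1e3))
  p <- default_params()
  p$lambda_C <- NULL
  expect_error(validate_params(p), "lambda_C")
})
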