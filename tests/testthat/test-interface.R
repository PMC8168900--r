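test_that("parameter files round-trip exactly and bad keys are named", {
  p <- default_params(zeta_Tb = 4e6, lambda_T1Tr = 1e3)
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  p2 <- load_params(f)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-14)
  # a typo'd key is reported by name
  writeLines(c("theta: 0.5", "lambda_Cee: 0.3"), f)
  expect_error(load_params(f), "lambda_Cee")
  expect_error(load_params(tempfile()), "not found")
})

test_that("the shipped default parameter file and presets load", {
  f <- system.file("extdata", "params_default.yaml", package = "tumorpde")
  expect_true(nzchar(f))
  p <- load_params(f)
  expect_equal(unclass(p), unclass(default_params()), tolerance = 1e-14)
  expect_warning(load_params(f, warn_placeholders = TRUE), "placeholder")
  # preset files agree with the in-code table
  for (nm in scenario_preset()$cancer) {
    y <- yaml::read_yaml(system.file("extdata", paste0("preset_", nm, ".yaml"),
                                     package = "tumorpde"))
    pr <- scenario_preset(nm)
    expect_equal(y$lambda_T1Tr, pr$lambda_T1Tr)
    expect_equal(y$zeta_Tb, pr$zeta_Tb)
    expect_equal(y$t0, pr$t0)
    expect_equal(y$horizon, pr$horizon)
  }
  cfgs <- load_config(preset = "colon")
  expect_equal(cfgs$preset$t0, 6)
  # inline override is reflected in the returned parameters
  cfgs2 <- load_config(overrides = list(lambda_T1Tr = 6))
  expect_equal(cfgs2$params$lambda_T1Tr, 6)
  expect_error(load_config(overrides = list(bogus = 1)), "bogus")
})

test_that("fixtures are reproducible and behave as labelled", {
  a <- make_fixture("random-state", seed = 42)
  b <- make_fixture("random-state", seed = 42)
  expect_identical(a$state, b$state)
  expect_identical(a$R, b$R)
  d <- make_fixture("random-state", seed = 43)
  expect_false(identical(a$state, d$state))
  fz <- make_fixture("frozen-params")
  rates <- grep("^lambda_|^mu_", names(fz), value = TRUE)
  expect_true(all(unlist(fz[rates]) == 0))
  lo <- make_fixture("logistic-only-params")
  expect_gt(lo$lambda_C, 0)
  expect_gt(lo$mu_C, 0)
  others <- setdiff(grep("^lambda_|^mu_", names(lo), value = TRUE),
                    c("lambda_C", "mu_C"))
  expect_true(all(unlist(lo[others]) == 0))
  expect_error(make_fixture("nope"), "arg")
})

test_that("trajectory CSV carries the documented header", {
  p <- make_fixture("logistic-only-params")
  ts <- tumor_state(list(C = p$theta), R = 0.1, N = 9, p = p)
  tr <- simulate_tumor(ts, p, treatment_schedule("control", 0, 0),
                       solver_config(N = 9, dt = 0.01), t_end = 2)
  f <- tempfile(fileext = ".csv"); fs <- tempfile(fileext = ".csv")
  write_trajectory(tr, f, snapshot_path = fs)
  got <- utils::read.csv(f)
  expect_identical(names(got)[1:3], c("t_days", "R_cm", "volume_cm3"))
  expect_true("Tr_avg_g_per_cm3" %in% names(got))
  snap <- utils::read.csv(fs)
  expect_identical(names(snap), c("t", "rho", "species", "value"))
  expect_equal(nrow(snap), 9 * 16)
})

test_that("map writer emits JSON with axes, matrix and metadata plus long CSV", {
  m <- structure(list(axis1 = c(1, 2), axis2 = c(3, 4, 5),
                      efficacy = matrix(1:6, 2, 3), failures = list(),
                      meta = list(kind = "synthetic")),
                 class = "efficacy_map")
  fj <- tempfile(fileext = ".json"); fc <- tempfile(fileext = ".csv")
  write_map(m, fj, fc)
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(j$axis1, c(1, 2))
  expect_equal(j$efficacy, matrix(1:6, 2, 3))
  long <- utils::read.csv(fc)
  expect_equal(nrow(long), 6)
  expect_identical(names(long), c("axis1", "axis2", "efficacy_pct"))
})

test_that("the command line dispatches, writes a manifest, and rejects junk", {
  out <- tempfile()
  st <- cli_main(c("simulate", "--preset", "colon", "--arm", "antiPD1",
                   "--out", out, "--n-grid", "9", "--dt", "0.01"))
  expect_identical(st, 0L)
  expect_true(file.exists(file.path(out, "trajectory_colon_antiPD1.csv")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(man$outputs[[1]]$file, "trajectory_colon_antiPD1.csv")
  expect_true(nzchar(man$outputs[[1]]$md5))
  expect_identical(cli_main(c("frobnicate")), 1L)
  expect_identical(cli_main(character()), 1L)
  expect_identical(cli_main(c("simulate", "--arm", "bogus")), 1L)
  out2 <- tempfile()
  st2 <- cli_main(c("fixtures", "--kind", "frozen-params", "--out", out2))
  expect_identical(st2, 0L)
  expect_true(file.exists(file.path(out2, "fixture_frozen-params.csv")))
})
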