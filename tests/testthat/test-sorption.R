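test_that("gravimetric moisture and basis conversions are exact", {
  expect_equal(moisture_wb_from_weights(1.0000, 0.9642), 3.58)
  expect_equal(moisture_wb_from_weights(2, 2), 0)
  expect_equal(moisture_wb_from_weights(2, 1), 50)
  expect_error(moisture_wb_from_weights(-1, 0.5), "positive")
  expect_error(moisture_wb_from_weights(1, 1.2), "exceed")

  expect_equal(convert_basis(moisture_value(5.66, "wet_percent"),
                             "dry_ratio")$value, 0.0566 / 0.9434)
  expect_equal(convert_basis(moisture_value(0, "wet_percent"),
                             "dry_ratio")$value, 0)
  expect_equal(convert_basis(moisture_value(0.0622, "dry_ratio"),
                             "wet_percent")$value, 0.0622 / 1.0622 * 100)
  expect_error(moisture_value(100, "wet_percent"))

  # involution: dry -> wet -> dry identity to 1e-12
  for (m in c(0.001, 0.06, 0.3, 1.5)) {
    back <- convert_basis(convert_basis(moisture_value(m, "dry_ratio"),
                                        "wet_percent"), "dry_ratio")
    expect_equal(back$value, m, tolerance = 1e-12)
  }
})

test_that("GAB evaluation matches the closed formula and rejects the pole", {
  p <- gab_params(0.06, 1.10, 0.99)
  expect_equal(gab_moisture(p, 0), 0)
  expect_equal(gab_moisture(p, 0.5), oracle_gab(0.06, 1.10, 0.99, 0.5))
  expect_equal(gab_moisture(p, 0.5), 0.0616418, tolerance = 1e-6)
  expect_equal(gab_moisture(p, 0.48), 0.0570511, tolerance = 1e-6)
  expect_error(gab_moisture(p, 1.5), "pole")
  expect_error(gab_params(0.06, 1.1, 1.2), "\\(0, 1\\)")
})

test_that("GAB isotherm is strictly increasing in a_w for valid parameters", {
  set.seed(11)
  for (i in 1:20) {
    p <- gab_params(runif(1, 0.01, 0.3), runif(1, 0.2, 50), runif(1, 0.3, 0.995))
    M <- gab_moisture(p, seq(0, 0.95, length.out = 200))
    expect_true(all(diff(M) > 0))
  }
})

test_that("fit_gab recovers generating parameters on noiseless data", {
  truth <- gab_params(0.06, 1.10, 0.99)
  data <- gen_isotherm(truth, seq(0.1, 0.9, by = 0.1), noise_sd = 0)
  fit <- fit_gab(data)
  expect_equal(fit$params$m0, 0.06, tolerance = 1e-3)
  expect_equal(fit$params$C, 1.10, tolerance = 1e-3)
  expect_equal(fit$params$b, 0.99, tolerance = 1e-3)
  expect_lt(fit$diagnostics$rmse, 1e-8)
  expect_true(fit$diagnostics$converged)

  expect_error(fit_gab(data.frame(aw = seq(0.1, 0.9, 0.1),
                                  moisture_db = 0)), "degenerate")
  expect_error(fit_gab(data[1:3, ]), "at least 4")
})

test_that("fit_gab beats a coarse grid-search oracle on random instances", {
  set.seed(7)
  for (i in 1:5) {
    truth <- list(m0 = runif(1, 0.03, 0.15), C = runif(1, 0.5, 5),
                  b = runif(1, 0.6, 0.95))
    p <- gab_params(truth$m0, truth$C, truth$b)
    data <- gen_isotherm(p, seq(0.05, 0.9, length.out = 10), noise_sd = 0)
    fit <- fit_gab(data)
    grid <- oracle_grid_gab(data, truth)
    sse_fit <- sum(fit$diagnostics$residuals^2)
    expect_lte(sse_fit, grid$sse + 1e-12)
    # within the grid resolution of the truth
    res <- abs(unlist(grid$params) - unlist(truth))
    expect_true(all(abs(c(fit$params$m0 - truth$m0, fit$params$C - truth$C,
                          fit$params$b - truth$b)) <= res + 1e-6))
  }
})

test_that("fit_gab is unbiased at instrument noise scale", {
  truth <- gab_params(0.06, 1.10, 0.99)
  est <- t(vapply(1:100, function(s) {
    d <- gen_isotherm(truth, seq(0.1, 0.9, by = 0.1), noise_sd = 0.002,
                      seed = s)
    f <- tryCatch(fit_gab(d), error = function(e) NULL)
    if (is.null(f)) c(NA, NA, NA)
    else c(f$params$m0, f$params$C, f$params$b)
  }, numeric(3)))
  means <- colMeans(est, na.rm = TRUE)
  expect_equal(means[1], 0.06, tolerance = 0.1)
  expect_equal(means[2], 1.10, tolerance = 0.1)
  expect_equal(means[3], 0.99, tolerance = 0.1)
})

test_that("monolayer activity and isotherm inversion agree with bisection", {
  p <- gab_params(0.06, 1.10, 0.99)
  aw0_oracle <- oracle_bisect(function(a)
    oracle_gab(0.06, 1.10, 0.99, a) - 0.06, 1e-6, 0.95)
  expect_equal(monolayer_activity(p), aw0_oracle, tolerance = 1e-6)
  expect_equal(monolayer_activity(p), 0.4930187, tolerance = 1e-5)

  expect_equal(invert_gab(p, 0.0622),
               oracle_bisect(function(a)
                 oracle_gab(0.06, 1.10, 0.99, a) - 0.0622, 1e-6, 0.95),
               tolerance = 1e-6)
  expect_equal(invert_gab(p, 0), 0)
  expect_equal(invert_gab(p, gab_moisture(p, 0.3)), 0.3, tolerance = 1e-6)
  expect_error(invert_gab(p, 10), "attainable")

  # unreachable monolayer: m0 above the whole isotherm on (0, 0.95]
  flat <- gab_params(0.2, 0.5, 0.3)
  expect_error(monolayer_activity(flat), "never reaches")

  # near-saturated C limit checked against a grid-scan oracle
  pc <- gab_params(0.05, 1e6, 0.9)
  grid <- seq(1e-4, 0.95, length.out = 20001)
  aw_grid <- grid[which.min(abs(oracle_gab(0.05, 1e6, 0.9, grid) - 0.05))]
  expect_lt(abs(monolayer_activity(pc) - aw_grid), 0.95 / 20000)
})

test_that("invert_gab round-trips for random moistures", {
  set.seed(21)
  p <- gab_params(0.08, 2.5, 0.9)
  M <- runif(100, 1e-4, gab_moisture(p, 0.95) * 0.999)
  for (m in M) expect_equal(gab_moisture(p, invert_gab(p, m)), m,
                            tolerance = 1e-6)
})

test_that("equilibrium detection matches a brute-force sliding window", {
  # constant mass: equilibrated immediately
  t <- seq(0, 20, by = 1 / 3)
  eq <- detect_equilibrium(data.frame(time_h = t, mass_g = rep(5, length(t))))
  expect_true(eq$reached)
  expect_equal(eq$t_eq, 0)

  # exponential approach: variation drops under 0.01% only late in the run
  t2 <- seq(0, 60, by = 1 / 3)
  d <- data.frame(time_h = t2, mass_g = 5 + 0.5 * exp(-0.15 * t2))
  got <- detect_equilibrium(d)
  want <- oracle_equilibrium(d$time_h, d$mass_g)
  expect_true(got$reached)
  expect_equal(got$t_eq, want$t_eq)
  expect_gt(got$t_eq, 20)

  # monotone 1%/h ramp never equilibrates
  ramp <- data.frame(time_h = t, mass_g = 5 * (1 + 0.01 * t))
  expect_false(detect_equilibrium(ramp)$reached)

  expect_error(detect_equilibrium(data.frame(time_h = 0:3, mass_g = 5:8)),
               "shorter")
})

test_that("isotherm CSV IO and fit records round-trip", {
  truth <- gab_params(0.06, 1.10, 0.99)
  d <- gen_isotherm(truth, noise_sd = 0)
  f <- file.path(tempdir(), "iso.csv")
  write.csv(d, f, row.names = FALSE)
  expect_equal(read_isotherm_csv(f), d)

  fit <- fit_gab(d)
  js <- fit_record_json(fit$params, fit$diagnostics)
  rec <- jsonlite::fromJSON(js)
  expect_equal(rec$parameters$m0, fit$params$m0)
  expect_equal(rec$rmse, fit$diagnostics$rmse)
  expect_equal(rec$n_obs, 9)
})
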