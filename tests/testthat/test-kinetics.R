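# printed kinetic parameter rows of the emulated study
table1 <- list(`11` = c(3.5, 2.8, 0.08), `32` = c(3.5, 5.8, 0.18),
               `65` = c(3.3, 14.7, 0.15))
table2 <- list(`11` = c(0.008, 0.124, 0.13), `32` = c(0.005, 0.118, 0.08),
               `65` = c(0.002, 0.101, 0.07))
table3 <- list(`11` = c(5.07, 0.38), `32` = c(5.07, 0.72),
               `65` = c(5.08, 2.11))
abs_times <- c(3, 10, 20, 30, 45, 60, 120)

test_that("forward kinetic models evaluate exactly", {
  p <- afo_params(3.3, 14.7, 0.15)
  expect_equal(asymptotic_first_order(p, 0), 3.3)
  expect_equal(asymptotic_first_order(p, 20), 14.1324, tolerance = 1e-4)
  expect_equal(asymptotic_first_order(p, 500), 14.7, tolerance = 1e-8)

  d <- exp_decay_params(5.07, 0)
  expect_equal(exp_decay(d, c(0, 50, 500)), rep(5.07, 3))
  d2 <- exp_decay_params(5.08, 2.11e-4)
  expect_equal(exp_decay(d2, 0), 5.08)
  expect_equal(exp_decay(d2, 135), 4.9373, tolerance = 1e-4)

  expect_error(afo_params(3, 3, 0.1), "differ")
  expect_error(afo_params(3, 5, -1), "> 0")
})

test_that("asymptotic response is monotone and bounded by its asymptotes", {
  set.seed(41)
  for (i in 1:20) {
    Y0 <- runif(1, 0, 10); Yinf <- Y0 + sample(c(-1, 1), 1) * runif(1, 0.5, 10)
    k <- runif(1, 0.01, 2)
    p <- afo_params(Y0, Yinf, k)
    # grid spans five characteristic times; beyond that the exponential
    # underflows and consecutive values are bitwise equal
    y <- asymptotic_first_order(p, seq(0, 5 / k, length.out = 200))
    if (Yinf > Y0) expect_true(all(diff(y) > 0)) else
      expect_true(all(diff(y) < 0))
    expect_true(all(y >= min(Y0, Yinf) - 1e-12 & y <= max(Y0, Yinf) + 1e-12))
  }
})

test_that("noiseless round-trips recover every printed parameter row", {
  for (key in names(table1)) {
    v <- table1[[key]]
    s <- gen_kinetic_series(afo_params(v[1], v[2], v[3]), 0:30, 0, 1, 1,
                            "moisture", as.numeric(key))[[1]]
    f <- fit_asymptotic_first_order(s)
    expect_equal(f$params$Y0, v[1], tolerance = 1e-3)
    expect_equal(f$params$Yinf, v[2], tolerance = 1e-3)
    expect_equal(f$params$k, v[3], tolerance = 1e-3)
  }
  for (key in names(table2)) {
    v <- table2[[key]]
    s <- gen_kinetic_series(afo_params(v[1], v[2], v[3]), abs_times, 0, 1, 1,
                            "abs420", as.numeric(key))[[1]]
    f <- fit_asymptotic_first_order(s)
    expect_equal(f$params$k, v[3], tolerance = 1e-3)
    expect_equal(f$params$Yinf, v[2], tolerance = 1e-3)
  }
  for (key in names(table3)) {
    v <- table3[[key]]
    tgrid <- seq(0, 4 / v[2], length.out = 25)
    s <- gen_kinetic_series(exp_decay_params(v[1], v[2]), tgrid, 0, 1, 1,
                            "ph", as.numeric(key))[[1]]
    f <- fit_exp_decay(s)
    expect_equal(f$params$pH0, v[1], tolerance = 1e-3)
    expect_equal(f$params$k, v[2], tolerance = 1e-3)
  }
  # rate ratio across the driest and most humid conditions
  expect_equal(table3$`65`[2] / table3$`11`[2], 5.553, tolerance = 1e-3)
})

test_that("degenerate series are rejected", {
  flat <- kinetic_series(0:10, rep(5, 11), "moisture", "days")
  expect_error(fit_asymptotic_first_order(flat), "flat|unidentifiable")
  short <- kinetic_series(c(0, 1), c(5.1, 5.0), "ph", "days")
  expect_error(fit_exp_decay(short), "at least 3")
  expect_error(kinetic_series(c(0, 1, 1), 1:3, "moisture", "days"),
               "increasing")
  expect_error(kinetic_series(0:2, c(5, -1, 4), "ph", "days"), "pH")
})

test_that("fits beat a coarse grid-search oracle on small instances", {
  set.seed(17)
  for (i in 1:5) {
    truth <- list(Y0 = runif(1, 1, 5), Yinf = runif(1, 6, 15),
                  k = runif(1, 0.05, 0.5))
    t <- 0:15
    y <- truth$Yinf - (truth$Yinf - truth$Y0) * exp(-truth$k * t)
    f <- fit_asymptotic_first_order(list(times = t, values = y))
    grid <- oracle_grid_afo(t, y, truth)
    expect_lte(sum(f$diagnostics$residuals^2), grid$sse + 1e-12)
  }
})

test_that("parameter recovery at study noise scale is unbiased", {
  est <- t(vapply(1:200, function(s) {
    sl <- gen_kinetic_series(afo_params(3.3, 14.7, 0.15), 0:30, 0.11, 1,
                             seed = s, "moisture", 65)
    f <- fit_asymptotic_first_order(sl[[1]])
    c(f$params$Y0, f$params$Yinf, f$params$k)
  }, numeric(3)))
  mc_se <- apply(est, 2, sd) / sqrt(nrow(est))
  bias <- colMeans(est) - c(3.3, 14.7, 0.15)
  expect_true(all(abs(bias) < 4 * mc_se + c(0.02, 0.02, 0.002)))
  expect_lt(abs(mean(est[, 3]) - 0.15), 0.02)
})

test_that("closed-form times-to-level invert the forward curves", {
  p <- afo_params(3.3, 14.7, 0.15)
  expect_equal(time_to_level_asymptotic(p, 3.3), 0)
  t622 <- time_to_level_asymptotic(p, 6.22)
  expect_equal(t622, 1.9727, tolerance = 1e-4)
  expect_equal(asymptotic_first_order(p, t622), 6.22, tolerance = 1e-10)
  expect_error(time_to_level_asymptotic(afo_params(3.5, 2.8, 0.08), 5),
               "never reached")

  d <- exp_decay_params(5.08, 2.11e-4)
  expect_equal(time_to_level_decay(d, 5.0), 75.229, tolerance = 1e-3)
  expect_equal(time_to_level_decay(exp_decay_params(exp(1), 1), 1), 1)
  expect_warning(t0 <- time_to_level_decay(d, 5.2), "convention")
  expect_equal(t0, 0)
  expect_error(time_to_level_decay(exp_decay_params(5, 0), 4), "never")

  # closed form agrees with numeric root-finding on 100 random instances
  set.seed(23)
  for (i in 1:100) {
    Y0 <- runif(1, 0, 5); Yinf <- Y0 + sample(c(-1, 1), 1) * runif(1, 1, 10)
    k <- runif(1, 0.01, 1)
    p <- afo_params(Y0, Yinf, k)
    lvl <- Y0 + runif(1, 0.05, 0.95) * (Yinf - Y0)
    t_closed <- time_to_level_asymptotic(p, lvl)
    t_num <- uniroot(function(t) asymptotic_first_order(p, t) - lvl,
                     c(0, 1e4), tol = 1e-12)$root
    expect_equal(t_closed, t_num, tolerance = 1e-8)
  }
})

test_that("tidy kinetics CSV IO splits series and rejects mixed units", {
  cfg <- study_config(seed = 3)
  dir <- file.path(tempdir(), "kin-io")
  gen_study(cfg, dir)
  series <- read_kinetics_csv(file.path(dir, "kinetics.csv"))
  expect_length(series, 3 * 3 * 3)  # responses x ERH x replicates
  s <- series[["moisture_erh65_rep1"]]
  expect_s3_class(s, "kinetic_series")
  expect_equal(s$unit, "days")
  expect_equal(s$times, 0:19)

  bad <- data.frame(time = 0:4, value = 5:9, unit = c("days", "seconds",
                                                      "days", "days", "days"),
                    response = "moisture", erh = 11, replicate = 1)
  fb <- file.path(tempdir(), "bad.csv")
  write.csv(bad, fb, row.names = FALSE)
  expect_error(read_kinetics_csv(fb), "mixed time units")
})
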