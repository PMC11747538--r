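test_that("the default calibration carries the published coefficients and applies exactly", {
  mod <- default_calibration()
  expect_equal(mod$dur_latency_coef, 0.59)
  expect_equal(mod$dur_intercept, 0.26)
  expect_equal(mod$tst_slope, 0.73)
  expect_equal(mod$tst_intercept, 2.15)
  expect_equal(mod$provenance, "default")

  # duration stage, unclipped and clipped branches
  expect_equal(apply_duration_calibration(mod, 1.0, 6.0, 8.0),
               0.59 + 6.0 + 0.26)
  expect_equal(apply_duration_calibration(mod, 2.0, 7.5, 8.0), 8.0)
  # TST stage, unclipped and clipped branches
  expect_equal(apply_tst_calibration(mod, 5.0, 6.85), 0.73 * 5 + 2.15)
  expect_equal(apply_tst_calibration(mod, 7.0, 6.0), 6.0)

  # identity/zero models leave the inputs alone
  zero <- calibration_model(0, 0, 1, 0)
  expect_equal(apply_duration_calibration(zero, 1.3, 6.2, 9), 6.2)
  expect_equal(apply_tst_calibration(zero, 5.4, 6), 5.4)

  # serialization round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(mod, path)
  back <- read_calibration(path)
  expect_equal(back[c("dur_latency_coef", "dur_intercept", "tst_slope",
                      "tst_intercept", "provenance")],
               mod[c("dur_latency_coef", "dur_intercept", "tst_slope",
                     "tst_intercept", "provenance")])
  expect_error(calibration_model(0.6, 0.3, 0.7, 2, provenance = "default"),
               "built-in")
})

test_that("noise-free linear metrics recover the generating coefficients exactly", {
  paired <- linear_paired(n = 50, seed = 14)
  mod <- fit_calibration(paired)
  expect_equal(mod$dur_latency_coef, 0.59, tolerance = 1e-8)
  expect_equal(mod$dur_intercept, 0.26, tolerance = 1e-8)
  expect_equal(mod$tst_slope, 0.73, tolerance = 1e-8)
  expect_equal(mod$tst_intercept, 2.15, tolerance = 1e-8)
  expect_equal(mod$diagnostics$bias, 0)
  expect_lt(mod$diagnostics$rmse_duration, 1e-8)

  # closed-form normal-equations oracle for the two OLS stages
  s <- paired$onset_latency_test_h
  y <- paired$onset_latency_ref_h
  alpha <- (mean(s * y) - mean(s) * mean(y)) / (mean(s^2) - mean(s)^2)
  beta <- mean(y) - alpha * mean(s)
  expect_equal(mod$diagnostics$alpha, alpha, tolerance = 1e-10)
  expect_equal(mod$diagnostics$beta, beta, tolerance = 1e-10)
  tt <- paired$tst_test_h
  tr <- paired$tst_ref_h
  sl <- (mean(tt * tr) - mean(tt) * mean(tr)) / (mean(tt^2) - mean(tt)^2)
  expect_equal(mod$tst_slope, sl, tolerance = 1e-10)
  expect_equal(mod$tst_intercept, mean(tr) - sl * mean(tt), tolerance = 1e-10)
})

test_that("the bias grid search matches exhaustive enumeration with its tie-break", {
  paired <- linear_paired(n = 30, sd_lat = 0.05, sd_tst = 0.05, seed = 6)
  grid <- seq(-5, 5, by = 0.1) / 60
  mod <- fit_duration_calibration(paired, grid)
  a <- mod$diagnostics$alpha
  b0 <- mod$diagnostics$beta
  dstar <- paired$duration_test_h + (1 - a) * paired$onset_latency_test_h - b0
  iccs <- vapply(grid, function(b) {
    brute_icc(cbind(pmin(dstar + b, paired$tib_h), paired$duration_ref_h),
              "absolute")
  }, numeric(1))
  best <- max(iccs)
  cand <- grid[iccs == best]
  want <- cand[order(abs(cand), cand)][1]
  expect_equal(mod$diagnostics$bias, want)
  expect_equal(mod$diagnostics$icc_duration, best, tolerance = 1e-10)
  expect_true(abs(mod$diagnostics$bias) <= 5 / 60 + 1e-12)
})

test_that("identical devices need essentially no correction", {
  p <- linear_paired(n = 40, a = 1, b = 0, tst_slope = 1, tst_intercept = 0,
                     seed = 23)
  mod <- fit_calibration(p)
  expect_equal(mod$diagnostics$alpha, 1, tolerance = 1e-8)
  expect_equal(mod$diagnostics$beta, 0, tolerance = 1e-8)
  expect_equal(mod$dur_latency_coef, 0, tolerance = 1e-8)
  expect_lte(abs(mod$dur_intercept), 5 / 60 + 1e-12)
  cal <- apply_calibration(mod, p)
  expect_equal(cal$duration_cal_h, p$duration_test_h, tolerance = 1e-6)
  expect_equal(cal$tst_cal_h, p$tst_test_h, tolerance = 1e-6)
})

test_that("fitted coefficients recover the generator truth through the epoch pipeline", {
  # low noise, n = 64
  p64 <- pair_nights(derive_cohort_metrics(generate_cohort(
    recovery_config(seed = 17))))
  m64 <- fit_calibration(p64)
  expect_lt(abs(m64$dur_latency_coef - 0.59), 0.05)
  expect_lt(abs(m64$dur_intercept - 0.26), 0.08)
  expect_lt(abs(m64$tst_slope - 0.73), 0.05)
  expect_lt(abs(m64$tst_intercept - 2.15), 0.15)

  # convergence: larger cohort, tighter recovery of the latency relation
  p640 <- pair_nights(derive_cohort_metrics(generate_cohort(
    recovery_config(seed = 18, n_participants = 10,
                    nights_range = c(64L, 64L), total_nights = 640))))
  m640 <- fit_calibration(p640)
  expect_lt(abs(m640$dur_latency_coef - 0.59), 0.025)
  expect_lt(abs(m640$tst_slope - 0.73), 0.025)
  expect_lt(abs(m640$tst_intercept - 2.15), 0.08)
})

test_that("zero-noise generation recovers the coefficients exactly on latent metrics", {
  coh <- generate_cohort(recovery_config(
    seed = 19, noise_sd_latency = 0, noise_sd_tst = 0,
    offset_latency_mean_test = 0))
  lat <- latent_metrics(coh)
  mod <- fit_calibration(lat)
  expect_equal(mod$dur_latency_coef, 0.59, tolerance = 1e-8)
  expect_equal(mod$dur_intercept, 0.26, tolerance = 1e-8)
  expect_equal(mod$tst_slope, 0.73, tolerance = 1e-8)
  expect_equal(mod$tst_intercept, 2.15, tolerance = 1e-8)
  expect_equal(mod$diagnostics$bias, 0)
})

test_that("degenerate cohorts are rejected", {
  p <- linear_paired(n = 10, seed = 3)
  p$onset_latency_test_h <- 1.0
  expect_error(fit_duration_calibration(p), "constant")
  p2 <- linear_paired(n = 10, seed = 3)
  p2$tst_test_h <- 4
  expect_error(fit_tst_calibration(p2), "constant")
  expect_error(fit_calibration(linear_paired(n = 2, seed = 1)), "at least 3")
})

test_that("clipping contract holds for every night under arbitrary models", {
  coh <- generate_cohort(cohort_config(
    n_participants = 5, nights_range = c(10L, 20L), total_nights = 75,
    seed = 77, noise_sd_latency = 0.3, noise_sd_tst = 0.5))
  paired <- pair_nights(derive_cohort_metrics(coh))
  models <- list(
    default_calibration(),
    fit_calibration(paired),
    calibration_model(1, 3, 1, 5),     # aggressive: forces the clips
    calibration_model(0, -2, 0.5, -10) # pathological: exercises the TST floor
  )
  for (mod in models) {
    cal <- apply_calibration(mod, paired)
    expect_true(all(cal$duration_cal_h <= paired$tib_h + 1e-12))
    expect_true(all(cal$tst_cal_h <= cal$duration_cal_h + 1e-12))
    expect_true(all(cal$tst_cal_h >= 0))
  }
})
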