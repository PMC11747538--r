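# Fixture matrices shared with the reference ICC implementation; the
# frozen estimates/CIs below were produced by that implementation on
# exactly these values (CIs at its printed 2-decimal precision).
fix10 <- matrix(c(6.10, 5.90, 7.25, 7.05, 5.80, 6.20, 6.95, 6.40,
                  7.60, 7.10, 6.40, 6.55, 5.95, 5.50, 7.10, 6.85,
                  6.70, 6.90, 6.20, 5.75), ncol = 2, byrow = TRUE)
fix6 <- matrix(c(5.52, 4.80, 6.73, 5.95, 6.10, 5.20, 5.90, 5.55,
                 6.40, 5.60, 6.05, 5.15), ncol = 2, byrow = TRUE)
fix8 <- matrix(c(7.0, 6.1, 6.2, 5.4, 8.1, 7.0, 5.5, 4.9, 6.8, 6.0,
                 7.4, 6.3, 6.0, 5.2, 7.9, 6.9), ncol = 2, byrow = TRUE)

test_that("two-way mean squares match hand ANOVA and the brute-force oracle", {
  ms <- two_way_mean_squares(cbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(ms$ms_rows, 2.0)
  expect_equal(ms$ms_cols, 1.5)
  expect_equal(ms$ms_err, 0)

  same <- cbind(c(4, 5, 6), c(4, 5, 6))
  ms2 <- two_way_mean_squares(same)
  expect_equal(ms2$ms_err, 0)
  expect_equal(ms2$ms_cols, 0)

  withr::with_seed(31, {
    for (i in 1:40) {
      m <- random_ratings(sample(3:30, 1))
      got <- two_way_mean_squares(m)
      want <- brute_mean_squares(m)
      expect_equal(got$ms_rows, want$msr, tolerance = 1e-10)
      expect_equal(got$ms_cols, want$msc, tolerance = 1e-10)
      expect_equal(got$ms_err, want$mse, tolerance = 1e-10)
    }
    # independent route: aov() decomposition
    m <- random_ratings(12)
    df <- data.frame(y = as.vector(m),
                     row = factor(rep(1:12, 2)),
                     col = factor(rep(1:2, each = 12)))
    tab <- summary(stats::aov(y ~ row + col, data = df))[[1]]
    got <- two_way_mean_squares(m)
    expect_equal(got$ms_rows, tab["row", "Mean Sq"], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(got$ms_cols, tab["col", "Mean Sq"], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(got$ms_err, tab["Residuals", "Mean Sq"], tolerance = 1e-10,
                 ignore_attr = TRUE)
  })

  expect_error(two_way_mean_squares(cbind(1:2, 2:3)), "3 rows")
  expect_error(two_way_mean_squares(cbind(c(1, NA, 3), c(2, 3, 4))),
               "missing")
})

test_that("ICC point estimates match the reference implementation on shared fixtures", {
  cases <- list(
    list(m = fix10, abs = 0.814984650060, con = 0.842485839393,
         abs_ci = c(0.42, 0.95), con_ci = c(0.49, 0.96)),
    list(m = fix6, abs = 0.335875551182, con = 0.876245396108,
         abs_ci = c(-0.03, 0.83), con_ci = c(0.36, 0.98)),
    list(m = fix8, abs = 0.633946501727, con = 0.979277826033,
         abs_ci = c(-0.02, 0.93), con_ci = c(0.90, 1.00))
  )
  for (cs in cases) {
    a <- icc_single(cs$m, "absolute")
    k <- icc_single(cs$m, "consistency")
    expect_equal(a$estimate, cs$abs, tolerance = 1e-6)
    expect_equal(k$estimate, cs$con, tolerance = 1e-6)
    expect_equal(round(c(a$ci_low, a$ci_high), 2), cs$abs_ci)
    expect_equal(round(c(k$ci_low, k$ci_high), 2), cs$con_ci)
  }
})

test_that("perfect agreement and pure additive bias separate the two ICC forms", {
  same <- cbind(c(4, 5, 6, 7), c(4, 5, 6, 7))
  for (form in c("absolute", "consistency")) {
    r <- icc_single(same, form)
    expect_equal(r$estimate, 1)
    expect_equal(r$ci_high, 1)
  }
  shifted <- cbind(c(4, 5, 6, 7), c(4, 5, 6, 7) + 0.8)
  expect_equal(icc_single(shifted, "consistency")$estimate, 1)
  expect_lt(icc_single(shifted, "absolute")$estimate, 1)

  # consistency invariant under a column shift; absolute strictly decays
  withr::with_seed(5, m <- random_ratings(20))
  base_con <- icc_single(m, "consistency")$estimate
  prev_abs <- icc_single(m, "absolute")$estimate
  for (shift in c(0.5, 1, 2, 4)) {
    ms <- m
    ms[, 2] <- m[, 2] + shift
    expect_equal(icc_single(ms, "consistency")$estimate, base_con,
                 tolerance = 1e-12)
    cur <- icc_single(ms, "absolute")$estimate
    expect_lt(cur, prev_abs)
    prev_abs <- cur
  }
  expect_error(icc_single(matrix(5, 3, 2)), "zero variance")
})

test_that("estimates agree with the brute-force oracle on random matrices", {
  withr::with_seed(99, {
    for (i in 1:60) {
      m <- random_ratings(sample(3:64, 1))
      for (form in c("absolute", "consistency")) {
        r <- icc_single(m, form)
        expect_equal(r$estimate, brute_icc(m, form), tolerance = 1e-10)
        expect_lte(r$ci_low, r$estimate)
        expect_gte(r$ci_high, r$estimate)
      }
    }
  })
})

test_that("a known two-way variance structure is estimated consistently", {
  # between-row variance 4, residual 1, no column effect: ICC = 4/5
  withr::with_seed(12, {
    n <- 4000
    m <- stats::rnorm(n, 0, 2) + matrix(stats::rnorm(2 * n, 0, 1), n, 2)
  })
  for (form in c("absolute", "consistency")) {
    est <- icc_single(m, form)$estimate
    expect_equal(est, 0.8, tolerance = 0.04)
    expect_equal(est, brute_icc(m, form), tolerance = 1e-10)
  }
})

test_that("Bland-Altman summaries follow the test-minus-reference convention", {
  z <- bland_altman_stats(c(5, 6), c(5, 6))
  expect_equal(z$mean_diff, 0)
  expect_equal(z$max_diff, 0)
  expect_equal(z$min_diff, 0)

  b <- bland_altman_stats(c(5, 6, 7), c(6, 6, 6))
  expect_equal(b$mean_diff, 0)
  expect_equal(b$max_diff, 1)
  expect_equal(b$min_diff, -1)
  expect_equal(b$sd_diff, 1)
  expect_equal(b$loa_low, -1.96)
  expect_equal(b$loa_high, 1.96)

  withr::with_seed(4, {
    for (i in 1:20) {
      x <- stats::rnorm(10, 6)
      y <- stats::rnorm(10, 6.5)
      s <- bland_altman_stats(x, y)
      expect_lte(s$min_diff, s$mean_diff)
      expect_gte(s$max_diff, s$mean_diff)
    }
  })
  expect_error(bland_altman_stats(1, 1), "at least 2")
  expect_error(bland_altman_stats(1:3, 1:2), "equal length")
})

test_that("ICC labels follow the guideline bands", {
  expect_equal(classify_icc(0.69), "moderate")
  expect_equal(classify_icc(0.91), "excellent")
  expect_equal(classify_icc(0.78), "good")
  expect_equal(classify_icc(c(-0.2, 0.49, 0.5, 0.749, 0.75, 0.899, 0.9, 1)),
               c("poor", "poor", "moderate", "moderate",
                 "good", "good", "excellent", "excellent"))
  expect_error(classify_icc(1.2), "exceed 1")
})
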