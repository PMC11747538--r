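# Independent brute-force oracles used across the suite.

# Two-way crossed mean squares computed term by term from the definitional
# sums of squares, with explicit loops (no shared code with the package).
brute_mean_squares <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) {
    ri <- sum(m[i, ]) / k
    ssr <- ssr + k * (ri - grand)^2
  }
  ssc <- 0
  for (j in seq_len(k)) {
    cj <- sum(m[, j]) / n
    ssc <- ssc + n * (cj - grand)^2
  }
  sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ri <- sum(m[i, ]) / k
      cj <- sum(m[, j]) / n
      sse <- sse + (m[i, j] - ri - cj + grand)^2
    }
  }
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

# Single-measure ICC point estimates from the brute-force mean squares.
brute_icc <- function(m, form) {
  ms <- brute_mean_squares(m)
  n <- nrow(m)
  k <- ncol(m)
  if (form == "consistency") {
    (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
  } else {
    (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
  }
}

# Naive single-pass epoch counter: walks the state sequence once and
# tallies the per-night metrics directly.
brute_metrics <- function(states, epoch_len_s) {
  n <- length(states)
  first <- NA
  last <- NA
  for (i in seq_len(n)) {
    if (states[i] == "S") {
      if (is.na(first)) first <- i
      last <- i
    }
  }
  stopifnot(!is.na(first))
  tst <- 0
  for (i in first:last) if (states[i] == "S") tst <- tst + 1
  h <- epoch_len_s / 3600
  list(
    tib_h = n * h,
    onset_latency_h = (first - 1) * h,
    offset_latency_h = (n - last) * h,
    duration_h = (last - first + 1) * h,
    tst_h = tst * h
  )
}

random_ratings <- function(n, k = 2) {
  r <- stats::rnorm(n, 6.5, 1)
  r + matrix(stats::rnorm(n * k, 0, 0.5), n, k) +
    rep(stats::rnorm(k, 0, 0.3), each = n)
}

# A synthetic paired-nights table built directly at the metrics level
# (no epoch realization): latencies and TSTs obey the supplied linear
# relations plus optional noise.
linear_paired <- function(n = 40, a = 0.41, b = -0.26,
                          tst_slope = 0.73, tst_intercept = 2.15,
                          sd_lat = 0, sd_tst = 0,
                          participants = 4, seed = NULL) {
  gen <- function() {
    tib <- round(stats::runif(n, 6, 9), 2)
    s <- stats::runif(n, 0.7, 2.2)
    lat_ref <- a * s + b + stats::rnorm(n, 0, sd_lat)
    dur_test <- tib - s
    dur_ref <- tib - lat_ref
    tst_ref <- dur_ref - stats::runif(n, 0.2, 1.2)
    tst_test <- (tst_ref - tst_intercept - stats::rnorm(n, 0, sd_tst)) /
      tst_slope
    tibble::tibble(
      participant_id = sprintf("p%02d", rep_len(seq_len(participants), n)),
      night_id = sprintf("n%03d", seq_len(n)),
      tib_h = tib,
      onset_latency_test_h = s, onset_latency_ref_h = lat_ref,
      offset_latency_test_h = 0, offset_latency_ref_h = 0,
      duration_test_h = dur_test, duration_ref_h = dur_ref,
      tst_test_h = tst_test, tst_ref_h = tst_ref
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Low-noise configuration used for parameter-recovery checks: the latency
# distribution is bounded away from the clip at zero so the linear
# cross-device relations are unclipped.
recovery_config <- function(seed, noise_sd_latency = 0.02,
                            noise_sd_tst = 0.05,
                            offset_latency_mean_test = 0.03, ...) {
  cohort_config(
    seed = seed,
    true_latency_mean = 1.5, latency_min = 0.8,
    noise_sd_latency = noise_sd_latency, noise_sd_tst = noise_sd_tst,
    offset_latency_mean_test = offset_latency_mean_test,
    ...
  )
}
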