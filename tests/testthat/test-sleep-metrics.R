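bed <- function(h = 23) as.POSIXct(sprintf("2024-03-01 %02d:00:00", h),
                                   tz = "UTC")

toy_states <- c("W", "W", "S", "S", "W", "S", "S", "S", "W", "W")

test_that("an all-sleep night yields zero latencies and TIB-long sleep", {
  b <- bed()
  ser <- new_epoch_series("test", 60, b, rep("S", 480))
  m <- derive_sleep_metrics(ser, b, b + 480 * 60)
  expect_equal(m$onset, b)
  expect_equal(m$offset, b + 480 * 60)
  expect_equal(m$onset_latency_h, 0)
  expect_equal(m$offset_latency_h, 0)
  expect_equal(m$duration_h, 8)
  expect_equal(m$tst_h, 8)
  expect_equal(m$tib_h, 8)
})

test_that("hand-counted toy night reproduces all seven metrics exactly", {
  b <- bed()
  m <- derive_sleep_metrics(new_epoch_series("test", 60, b, toy_states),
                            b, b + 600)
  expect_equal(m$tib_h, 10 / 60)
  expect_equal(m$onset, b + 2 * 60)         # first sleep epoch starts min 2
  expect_equal(m$offset, b + 8 * 60)        # last sleep epoch ends min 8
  expect_equal(m$onset_latency_h, 2 / 60)
  expect_equal(m$offset_latency_h, 2 / 60)
  expect_equal(m$duration_h, 6 / 60)
  expect_equal(m$tst_h, 5 / 60)             # one wake epoch inside
})

test_that("metrics are invariant to halving the epoch length", {
  b <- bed()
  m60 <- derive_sleep_metrics(new_epoch_series("test", 60, b, toy_states),
                              b, b + 600)
  split <- rep(toy_states, each = 2)
  m30 <- derive_sleep_metrics(new_epoch_series("ref", 30, b, split),
                              b, b + 600)
  for (col in c("tib_h", "onset_latency_h", "offset_latency_h",
                "duration_h", "tst_h")) {
    expect_equal(m30[[col]], m60[[col]], info = col)
  }
  expect_equal(m30$onset, m60$onset)
  expect_equal(m30$offset, m60$offset)

  # and on random nights
  withr::with_seed(11, {
    for (i in 1:20) {
      st <- sample(c("W", "S"), 40, replace = TRUE, prob = c(0.3, 0.7))
      if (!any(st == "S")) st[5] <- "S"
      a <- derive_sleep_metrics(new_epoch_series("d", 60, b, st), b, b + 2400)
      h <- derive_sleep_metrics(
        new_epoch_series("d", 30, b, rep(st, each = 2)), b, b + 2400)
      expect_equal(h[4:7], a[4:7])
    }
  })
})

test_that("degenerate and malformed inputs raise the documented QC errors", {
  b <- bed()
  expect_error(
    derive_sleep_metrics(new_epoch_series("d", 60, b, rep("W", 10)),
                         b, b + 600),
    class = "sleepcal_no_sleep_epoch"
  )
  expect_error(
    derive_sleep_metrics(new_epoch_series("d", 60, b, toy_states), b, b),
    class = "sleepcal_marker_order"
  )
  expect_error(
    derive_sleep_metrics(new_epoch_series("d", 60, b, toy_states),
                         b, b + 900),
    class = "sleepcal_series_gap"
  )
  expect_error(
    derive_sleep_metrics(new_epoch_series("d", 60, b, toy_states),
                         as.POSIXct(NA), b + 600),
    class = "sleepcal_missing_marker"
  )
})

test_that("partition identity and brute-force agreement hold on random sequences", {
  b <- bed()
  withr::with_seed(7, {
    for (i in 1:300) {
      n <- sample(10:120, 1)
      len <- sample(c(30, 60), 1)
      st <- sample(c("W", "S"), n, replace = TRUE,
                   prob = c(stats::runif(1, 0.05, 0.6), 1))
      if (!any(st == "S")) st[sample(n, 1)] <- "S"
      m <- derive_sleep_metrics(new_epoch_series("d", len, b, st),
                                b, b + n * len)
      o <- brute_metrics(st, len)
      expect_equal(m$tib_h, o$tib_h)
      expect_equal(m$onset_latency_h, o$onset_latency_h)
      expect_equal(m$offset_latency_h, o$offset_latency_h)
      expect_equal(m$duration_h, o$duration_h)
      expect_equal(m$tst_h, o$tst_h)
      # identities
      expect_equal(m$onset_latency_h + m$duration_h + m$offset_latency_h,
                   m$tib_h)
      expect_lte(m$tst_h, m$duration_h)
      wake_inside <- m$duration_h - m$tst_h
      expect_equal(wake_inside == 0,
                   all(st[which(st == "S")[1]:max(which(st == "S"))] == "S"))
    }
  })
})

test_that("cohort-level derivation flags bad nights and excludes them", {
  coh <- generate_cohort(cohort_config(
    n_participants = 3, nights_range = c(3, 4), total_nights = 10, seed = 5))
  # sabotage: night 1 all wake on the test device; night 2 loses its ref series
  coh$nights$series[[1]]$test$states[] <- "W"
  coh$nights$series[[2]]$ref <- NULL
  metrics <- derive_cohort_metrics(coh)
  qc <- qc_flags(metrics)
  expect_setequal(qc$code, c("no_sleep_epoch", "series_gap"))
  flagged <- unique(qc$night_id[qc$participant_id == "p01"])
  got <- metrics[metrics$participant_id == "p01", ]
  expect_false(any(got$night_id %in% flagged))
  paired <- pair_nights(metrics)
  expect_equal(nrow(paired), 8)
  expect_true(all(abs(paired$onset_latency_test_h + paired$duration_test_h +
                        paired$offset_latency_test_h - paired$tib_h) < 1e-12))
})
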