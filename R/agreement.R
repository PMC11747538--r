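#' Two-way crossed mean squares without replication
#'
#' Decomposes an n x k ratings matrix (rows = nights pooled across
#' participants, columns = devices) into between-row, between-column and
#' residual mean squares — the variance components underlying the two-way
#' single-measurement intraclass correlation coefficients.
#'
#' @param m Numeric matrix, `n >= 3` rows, `k >= 2` columns, no missing
#'   cells.
#' @return An object of class `anova_squares`: list with `ms_rows` (MSR),
#'   `ms_cols` (MSC), `ms_err` (MSE), `n`, `k`.
#' @examples
#' two_way_mean_squares(cbind(c(1, 2, 3), c(2, 3, 4)))
#' @export
two_way_mean_squares <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("ratings matrix has missing cells", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) stop("need at least 3 rows (nights)", call. = FALSE)
  if (k < 2) stop("need at least 2 columns (devices)", call. = FALSE)
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  structure(
    list(ms_rows = ssr / (n - 1),
         ms_cols = ssc / (k - 1),
         ms_err = sse / ((n - 1) * (k - 1)),
         n = n, k = k),
    class = "anova_squares"
  )
}

#' @export
print.anova_squares <- function(x, ...) {
  cat(sprintf("<anova_squares> n = %d, k = %d\n  MSR %.6g  MSC %.6g  MSE %.6g\n",
              x$n, x$k, x$ms_rows, x$ms_cols, x$ms_err))
  invisible(x)
}

#' Two-way single-measurement intraclass correlation coefficient
#'
#' Point estimate and two-sided confidence interval for the
#' single-measurement ICC of a two-way model (rows = nights, columns =
#' devices), in either of its two forms:
#'
#' * **consistency**: `(MSR - MSE) / (MSR + (k-1) MSE)` — insensitive to a
#'   systematic device offset; CI from the exact F ratio `MSR/MSE` on
#'   `(n-1, (n-1)(k-1))` degrees of freedom.
#' * **absolute** agreement: `(MSR - MSE) / (MSR + (k-1) MSE +
#'   (k/n)(MSC - MSE))` — penalizes systematic offsets; CI by the
#'   Satterthwaite-approximated F interval standard for this form (the
#'   convention of the established ICC implementations), whose lower bound
#'   can be negative when the device offset is large.
#'
#' @param m Ratings matrix as in [two_way_mean_squares()] (for the usual
#'   dual-device case, an n x 2 matrix of hours).
#' @param form `"absolute"` (default) or `"consistency"`.
#' @param conf_level Two-sided confidence level (default 0.95).
#' @return An `icc_result`: list with `form`, `estimate`, `ci_low`,
#'   `ci_high`, `conf_level`, `n`, `k`, `label` (see [classify_icc()]) and
#'   the underlying `anova_squares`.
#' @examples
#' m <- cbind(c(6.1, 7.0, 6.4, 7.9), c(6.0, 7.2, 6.5, 7.7))
#' icc_single(m, "absolute")
#' @export
icc_single <- function(m, form = c("absolute", "consistency"),
                       conf_level = 0.95) {
  form <- match.arg(form)
  stopifnot(conf_level > 0, conf_level < 1)
  ms <- two_way_mean_squares(m)
  msr <- ms$ms_rows
  msc <- ms$ms_cols
  mse <- ms$ms_err
  n <- ms$n
  k <- ms$k
  alpha <- 1 - conf_level

  denom <- if (form == "consistency") {
    msr + (k - 1) * mse
  } else {
    msr + (k - 1) * mse + (k / n) * (msc - mse)
  }
  if (denom <= 0) {
    stop("ICC undefined: zero variance in the ratings matrix", call. = FALSE)
  }
  est <- (msr - mse) / denom

  if (mse == 0 && msc == 0) {
    # identical columns: perfect agreement, no sampling uncertainty left
    ci <- c(est, 1)
  } else if (form == "consistency") {
    fobs <- msr / mse
    df2 <- (n - 1) * (k - 1)
    if (!is.finite(fobs)) {
      ci <- c(1, 1)
    } else {
      fl <- fobs / stats::qf(1 - alpha / 2, n - 1, df2)
      fu <- fobs * stats::qf(1 - alpha / 2, df2, n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  } else {
    # Satterthwaite df for the agreement form
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    if (!is.finite(a) || !is.finite(b)) {
      ci <- c(est, 1)
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f1 <- stats::qf(1 - alpha / 2, n - 1, v)
      f2 <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f1 * mse) /
        (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f2 * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f2 * msr)
      ci <- c(lo, hi)
    }
  }
  ci[is.nan(ci)] <- est
  ci <- pmin(pmax(ci, -1), 1)
  ci <- c(min(ci[1], est), max(ci[2], est))

  structure(
    list(form = form, estimate = est, ci_low = ci[1], ci_high = ci[2],
         conf_level = conf_level, n = n, k = k,
         label = classify_icc(est), mean_squares = ms),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "<icc_result> two-way, %s, single measurement (n = %d, k = %d)\n  ICC = %.3f (%d%% CI %.3f to %.3f) — %s\n",
    x$form, x$n, x$k, x$estimate, round(100 * x$conf_level),
    x$ci_low, x$ci_high, x$label))
  invisible(x)
}

#' Bland-Altman difference summary
#'
#' Per-night differences are computed as test minus reference (so a
#' negative mean means the test device underestimates). Reports the mean,
#' extreme and SD of the differences plus the conventional 95% limits of
#' agreement (mean +/- 1.96 SD).
#'
#' @param test,ref Numeric vectors of paired measurements (hours), equal
#'   length >= 2.
#' @return A `bland_altman` object: list with `mean_diff`, `max_diff`,
#'   `min_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @examples
#' bland_altman_stats(c(5, 6, 7), c(6, 6, 6))
#' @export
bland_altman_stats <- function(test, ref) {
  if (length(test) != length(ref)) {
    stop("`test` and `ref` must have equal length", call. = FALSE)
  }
  if (length(test) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (anyNA(test) || anyNA(ref)) stop("missing values in pairs", call. = FALSE)
  d <- test - ref
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(mean_diff = m, max_diff = max(d), min_diff = min(d),
         sd_diff = s, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         n = length(d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d (test - ref)\n  mean %.3f h  [min %.3f, max %.3f]  LoA %.3f to %.3f\n",
    x$n, x$mean_diff, x$min_diff, x$max_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Qualitative label for an ICC estimate
#'
#' Standard reliability bands: below 0.5 poor, 0.5 to 0.75 moderate, 0.75
#' to 0.9 good, 0.9 and above excellent.
#'
#' @param estimate Numeric vector of ICC estimates (each <= 1).
#' @return Character vector of labels.
#' @examples
#' classify_icc(c(0.69, 0.78, 0.91))
#' @export
classify_icc <- function(estimate) {
  if (any(estimate > 1 + 1e-12, na.rm = TRUE)) {
    stop("an ICC estimate cannot exceed 1", call. = FALSE)
  }
  out <- character(length(estimate))
  out[estimate < 0.5] <- "poor"
  out[estimate >= 0.5 & estimate < 0.75] <- "moderate"
  out[estimate >= 0.75 & estimate < 0.9] <- "good"
  out[estimate >= 0.9] <- "excellent"
  out[is.na(estimate)] <- NA_character_
  out
}

#' Agreement summary for both sleep measures
#'
#' Convenience wrapper computing, for sleep duration and TST, both ICC
#' forms plus the Bland-Altman summary from a paired metrics table
#' ([pair_nights()]), optionally on calibrated test-device values.
#'
#' @param paired Paired metrics tibble.
#' @param conf_level Confidence level for the ICC intervals.
#' @param calibrated If `TRUE`, use the `duration_cal_h`/`tst_cal_h`
#'   columns (added by [apply_calibration()]) as the test-device values.
#' @return A nested list: `$duration` and `$tst`, each holding
#'   `icc_absolute`, `icc_consistency` and `bland_altman`.
#' @export
agreement_summary <- function(paired, conf_level = 0.95, calibrated = FALSE) {
  cols <- if (calibrated) {
    c(duration = "duration_cal_h", tst = "tst_cal_h")
  } else {
    c(duration = "duration_test_h", tst = "tst_test_h")
  }
  missing_cols <- setdiff(cols, names(paired))
  if (length(missing_cols) > 0) {
    stop("paired table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (measure in names(cols)) {
    test <- paired[[cols[[measure]]]]
    ref <- paired[[paste0(measure, "_ref_h")]]
    m <- cbind(test = test, ref = ref)
    out[[measure]] <- list(
      icc_absolute = icc_single(m, "absolute", conf_level),
      icc_consistency = icc_single(m, "consistency", conf_level),
      bland_altman = bland_altman_stats(test, ref)
    )
  }
  out
}
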