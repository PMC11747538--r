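#' Agreement plots for a paired metrics table
#'
#' `plot_device_scatter()` draws test-device against reference-device
#' values with the identity line; `plot_bland_altman()` draws per-night
#' differences (test - reference) against the pair means with the mean
#' difference and 95% limits of agreement.
#'
#' @param paired Paired metrics tibble ([pair_nights()]), with calibrated
#'   columns ([apply_calibration()]) when `calibrated = TRUE`.
#' @param measure `"duration"` or `"tst"`.
#' @param calibrated Plot calibrated test-device values.
#' @return A ggplot object.
#' @export
plot_device_scatter <- function(paired, measure = c("duration", "tst"),
                                calibrated = FALSE) {
  measure <- match.arg(measure)
  v <- agreement_columns(paired, measure, calibrated)
  df <- tibble::tibble(ref = paired[[v$ref]], test = paired[[v$test]])
  lim <- range(c(df$ref, df$test))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ref, y = .data$test)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(x = sprintf("reference %s (h)", measure),
                  y = sprintf("%s %s (h)",
                              if (calibrated) "calibrated test" else "test",
                              measure)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_device_scatter
#' @export
plot_bland_altman <- function(paired, measure = c("duration", "tst"),
                              calibrated = FALSE) {
  measure <- match.arg(measure)
  v <- agreement_columns(paired, measure, calibrated)
  ba <- bland_altman_stats(paired[[v$test]], paired[[v$ref]])
  df <- tibble::tibble(
    avg = (paired[[v$test]] + paired[[v$ref]]) / 2,
    diff = paired[[v$test]] - paired[[v$ref]]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = sprintf("mean of devices, %s (h)", measure),
                  y = "test - reference (h)") +
    ggplot2::theme_minimal()
}

agreement_columns <- function(paired, measure, calibrated) {
  test <- if (calibrated) paste0(measure, "_cal_h") else
    paste0(measure, "_test_h")
  ref <- paste0(measure, "_ref_h")
  for (col in c(test, ref)) {
    if (!col %in% names(paired)) {
      stop("paired table lacks column ", col, call. = FALSE)
    }
  }
  list(test = test, ref = ref)
}
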