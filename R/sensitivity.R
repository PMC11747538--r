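#' Leave-one-participant-out sensitivity analysis
#'
#' Quantifies how much the calibrated agreement depends on any single
#' participant. For each participant in turn, that participant's nights
#' are dropped and the absolute-agreement ICCs of calibrated duration and
#' TST are recomputed on the remaining nights, either
#'
#' * `mode = "fixed"`: applying the calibration fitted once on the full
#'   cohort (tests the generality of the fitted equations), or
#' * `mode = "refit"`: refitting the full two-stage calibration (including
#'   the bias-term grid search) on each subset (tests the stability of the
#'   fitting procedure).
#'
#' The analysis is deterministic given the cohort and mode. A subset too
#' small to fit or to support an ICC is reported as an undefined entry
#' with a diagnostic note (and a warning) and excluded from the ranges,
#' never silently dropped.
#'
#' @param paired Paired metrics tibble ([pair_nights()]) covering >= 3
#'   participants.
#' @param mode `"fixed"` or `"refit"`.
#' @param full_model Calibration fitted on the full cohort; required for
#'   `"fixed"` mode (fitted on the fly from `paired` when omitted).
#' @param bias_grid Bias grid passed to refits.
#' @param conf_level Confidence level for the per-subset ICC intervals.
#' @return A `sensitivity_result`: list with `mode`, `per_excluded`
#'   (tibble: `participant_id`, `icc_duration`, `icc_tst`, `n_nights`,
#'   `note`), `range_duration`, `range_tst`.
#' @export
leave_one_out <- function(paired, mode = c("fixed", "refit"),
                          full_model = NULL,
                          bias_grid = seq(-5, 5, by = 0.1) / 60,
                          conf_level = 0.95) {
  mode <- match.arg(mode)
  check_paired(paired, n_min = 3)
  participants <- unique(paired$participant_id)
  if (length(participants) < 3) {
    stop("leave-one-out needs at least 3 participants", call. = FALSE)
  }
  if (mode == "fixed" && is.null(full_model)) {
    full_model <- fit_calibration(paired, bias_grid)
  }

  rows <- vector("list", length(participants))
  for (i in seq_along(participants)) {
    p <- participants[i]
    sub <- paired[paired$participant_id != p, , drop = FALSE]
    res <- tryCatch({
      mod <- if (mode == "refit") fit_calibration(sub, bias_grid) else full_model
      cal <- apply_calibration(mod, sub)
      list(
        dur = icc_single(cbind(cal$duration_cal_h, cal$duration_ref_h),
                         "absolute", conf_level)$estimate,
        tst = icc_single(cbind(cal$tst_cal_h, cal$tst_ref_h),
                         "absolute", conf_level)$estimate,
        note = NA_character_
      )
    }, error = function(e) {
      warning(sprintf("subset excluding %s undefined: %s",
                      p, conditionMessage(e)), call. = FALSE)
      list(dur = NA_real_, tst = NA_real_, note = conditionMessage(e))
    })
    rows[[i]] <- tibble::tibble(
      participant_id = p,
      icc_duration = res$dur, icc_tst = res$tst,
      n_nights = nrow(sub), note = res$note
    )
  }
  per <- dplyr::bind_rows(rows)
  ok <- !is.na(per$icc_duration)
  if (!any(ok)) {
    stop("every leave-one-out subset was undefined", call. = FALSE)
  }
  structure(
    list(mode = mode,
         per_excluded = per,
         range_duration = range(per$icc_duration[ok]),
         range_tst = range(per$icc_tst[!is.na(per$icc_tst)])),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> leave-one-participant-out, mode = %s\n",
              x$mode))
  cat(sprintf("  duration ICC range %.3f-%.3f; TST ICC range %.3f-%.3f\n",
              x$range_duration[1], x$range_duration[2],
              x$range_tst[1], x$range_tst[2]))
  n_bad <- sum(!is.na(x$per_excluded$note))
  if (n_bad > 0) cat(sprintf("  %d undefined subset(s)\n", n_bad))
  invisible(x)
}
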