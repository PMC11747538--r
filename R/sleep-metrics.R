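#' Derive per-night sleep metrics from an epoch-level series
#'
#' Computes the seven per-night summaries from one device's scored
#' sleep/wake series and the participant-marked bedtime/risetime:
#'
#' * **TIB** (time in bed): risetime - bedtime;
#' * **sleep onset**: start of the first sleep-state epoch at/after bedtime;
#' * **sleep offset**: end boundary of the last sleep-state epoch before
#'   risetime (its start plus one epoch length -- one minute at 60 s
#'   epochs, 30 s at 30 s epochs);
#' * **onset latency** `S`: bedtime to onset; **offset latency**: offset to
#'   risetime;
#' * **sleep duration** `D`: onset to offset (intra-sleep wake included);
#' * **TST** `T`: total sleep-state epoch time between onset and offset.
#'
#' Epoch timestamps denote epoch start and intervals are half-open
#' `[start, start + epoch_len)`; only epochs whose start lies in
#' `[bedtime, risetime)` belong to the night, and the series must cover
#' that window exactly. All durations are returned in hours, so the
#' partition identity `tib = onset_latency + duration + offset_latency`
#' holds exactly at epoch resolution.
#'
#' @param series An `epoch_series` (see [new_epoch_series()]).
#' @param bedtime,risetime POSIXct event markers; `risetime > bedtime`.
#' @return A one-row tibble with columns `tib_h`, `onset`, `offset`,
#'   `onset_latency_h`, `offset_latency_h`, `duration_h`, `tst_h`.
#' @examples
#' bed <- as.POSIXct("2024-03-01 23:00:00", tz = "UTC")
#' ser <- new_epoch_series("test", 60, bed,
#'                         c("W", "W", "S", "S", "W", "S", "S", "S", "W", "W"))
#' derive_sleep_metrics(ser, bed, bed + 600)
#' @export
derive_sleep_metrics <- function(series, bedtime, risetime) {
  stopifnot(inherits(series, "epoch_series"))
  if (is.na(bedtime) || is.na(risetime)) {
    metrics_error("missing_marker", "bedtime or risetime is missing")
  }
  if (!(risetime > bedtime)) {
    metrics_error("marker_order", "risetime must be after bedtime")
  }
  len <- series$epoch_len
  n <- length(series$states)
  span <- as.numeric(difftime(risetime, bedtime, units = "secs"))
  if (abs(as.numeric(difftime(series$start, bedtime, units = "secs"))) > 1e-6 ||
      abs(n * len - span) > 1e-6) {
    metrics_error("series_gap",
                  "epoch series does not span [bedtime, risetime) exactly")
  }
  sleep_idx <- which(series$states == "S")
  if (length(sleep_idx) == 0) {
    metrics_error("no_sleep_epoch", "night contains no sleep-state epoch")
  }
  first <- sleep_idx[1]
  last <- sleep_idx[length(sleep_idx)]
  tst_epochs <- sum(sleep_idx >= first & sleep_idx <= last)

  tibble::tibble(
    tib_h = n * len / 3600,
    onset = bedtime + (first - 1) * len,
    offset = bedtime + last * len,
    onset_latency_h = (first - 1) * len / 3600,
    offset_latency_h = (n - last) * len / 3600,
    duration_h = (last - first + 1) * len / 3600,
    tst_h = tst_epochs * len / 3600
  )
}

metrics_error <- function(code, message) {
  rlang::abort(message, class = c(paste0("sleepcal_", code), "sleepcal_qc"))
}

qc_code <- function(cnd) {
  cls <- grep("^sleepcal_", setdiff(class(cnd), "sleepcal_qc"), value = TRUE)
  if (length(cls) > 0) sub("^sleepcal_", "", cls[1]) else "error"
}

#' Derive metrics for every night and device of a cohort
#'
#' Applies [derive_sleep_metrics()] to each device series of each night.
#' Nights failing a quality-control check (no sleep epoch, missing or
#' misordered markers, a series not covering the in-bed window) are
#' excluded from the returned metrics and recorded as flags, retrievable
#' with [qc_flags()]; flagged nights never reach the agreement or
#' calibration stages.
#'
#' @param cohort A `sleep_cohort` (generated or read from files).
#' @return A tibble with one row per night x device: `participant_id`,
#'   `night_id`, `device`, and the seven metric columns; QC flags are
#'   attached as the `"qc"` attribute.
#' @export
derive_cohort_metrics <- function(cohort) {
  stopifnot(inherits(cohort, "sleep_cohort"))
  nights <- cohort$nights
  devices <- unique(unlist(lapply(nights$series, names)))
  rows <- list()
  qc <- list()
  for (i in seq_len(nrow(nights))) {
    for (dev in devices) {
      ser <- nights$series[[i]][[dev]]
      key <- tibble::tibble(participant_id = nights$participant_id[i],
                            night_id = nights$night_id[i], device = dev)
      if (is.null(ser)) {
        qc[[length(qc) + 1L]] <- dplyr::mutate(
          key, code = "series_gap",
          message = "no epoch series for this device/night")
        next
      }
      res <- tryCatch(
        derive_sleep_metrics(ser, nights$bedtime[i], nights$risetime[i]),
        sleepcal_qc = function(cnd) cnd
      )
      if (inherits(res, "condition")) {
        qc[[length(qc) + 1L]] <- dplyr::mutate(
          key, code = qc_code(res), message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(key, res)
      }
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty_metrics()
  qc_tbl <- if (length(qc) > 0) {
    dplyr::bind_rows(qc)
  } else {
    tibble::tibble(participant_id = character(), night_id = character(),
                   device = character(), code = character(),
                   message = character())
  }
  # a flag on either device invalidates the whole night
  if (nrow(qc_tbl) > 0) {
    out <- dplyr::anti_join(out, qc_tbl,
                            by = c("participant_id", "night_id"))
  }
  attr(out, "qc") <- qc_tbl
  out
}

empty_metrics <- function() {
  tibble::tibble(
    participant_id = character(), night_id = character(),
    device = character(), tib_h = numeric(),
    onset = as.POSIXct(character(), tz = "UTC"),
    offset = as.POSIXct(character(), tz = "UTC"),
    onset_latency_h = numeric(), offset_latency_h = numeric(),
    duration_h = numeric(), tst_h = numeric()
  )
}

#' Quality-control flags attached to a metrics table
#'
#' @param metrics The result of [derive_cohort_metrics()].
#' @return A tibble of flags (`participant_id`, `night_id`, `device`,
#'   `code`, `message`); zero rows when every night passed.
#' @export
qc_flags <- function(metrics) {
  qc <- attr(metrics, "qc")
  if (is.null(qc)) {
    stop("`metrics` carries no QC attribute; was it built by derive_cohort_metrics()?",
         call. = FALSE)
  }
  qc
}

#' Pair the two devices' per-night metrics
#'
#' Pivots a long metrics table (one row per night x device) into the wide
#' paired layout used by the agreement and calibration stages: one row per
#' night with `_test_h` and `_ref_h` metric columns. Only nights measured
#' by both devices are kept.
#'
#' @param metrics Long metrics tibble from [derive_cohort_metrics()].
#' @param device_test,device_ref Device identifiers of the test and
#'   reference device (defaults `"test"` and `"ref"`, the generator's ids).
#' @return A tibble with one row per complete night.
#' @export
pair_nights <- function(metrics, device_test = "test", device_ref = "ref") {
  for (d in c(device_test, device_ref)) {
    if (!d %in% metrics$device) {
      stop(sprintf("device '%s' not present in metrics", d), call. = FALSE)
    }
  }
  keep <- c("participant_id", "night_id", "tib_h", "onset_latency_h",
            "offset_latency_h", "duration_h", "tst_h")
  mt <- metrics[metrics$device == device_test, keep]
  mr <- metrics[metrics$device == device_ref, keep]
  names(mt)[4:7] <- sub("_h$", "_test_h", names(mt)[4:7])
  names(mr)[4:7] <- sub("_h$", "_ref_h", names(mr)[4:7])
  paired <- dplyr::inner_join(mt, mr,
                              by = c("participant_id", "night_id"),
                              suffix = c("", "_refdev"))
  if (any(abs(paired$tib_h - paired$tib_h_refdev) > 1e-9)) {
    stop("devices disagree on TIB; markers are shared so spans must match",
         call. = FALSE)
  }
  dplyr::select(paired, -"tib_h_refdev")
}
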