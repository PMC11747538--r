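#' Write a cohort to the epoch/marker CSV schema
#'
#' Emits two artifacts: `epochs.csv` (`participant_id`, `night_id`,
#' `device_id`, `epoch_start` ISO-8601, `epoch_len_s`, `state` in
#' `{W, S}`) and `markers.csv` (`participant_id`, `night_id`, `bedtime`,
#' `risetime` ISO-8601). A write/read round trip is lossless.
#'
#' @param cohort A `sleep_cohort`.
#' @param epochs_path,markers_path Output CSV paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_cohort <- function(cohort, epochs_path, markers_path) {
  stopifnot(inherits(cohort, "sleep_cohort"))
  nights <- cohort$nights
  ep <- purrr::map_dfr(seq_len(nrow(nights)), function(i) {
    purrr::map_dfr(nights$series[[i]], function(ser) {
      n <- length(ser$states)
      tibble::tibble(
        participant_id = nights$participant_id[i],
        night_id = nights$night_id[i],
        device_id = ser$device_id,
        epoch_start = iso8601(ser$start + (seq_len(n) - 1) * ser$epoch_len),
        epoch_len_s = ser$epoch_len,
        state = ser$states
      )
    })
  })
  mk <- tibble::tibble(
    participant_id = nights$participant_id,
    night_id = nights$night_id,
    bedtime = iso8601(nights$bedtime),
    risetime = iso8601(nights$risetime)
  )
  readr::write_csv(ep, epochs_path)
  readr::write_csv(mk, markers_path)
  invisible(c(epochs = epochs_path, markers = markers_path))
}

iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_iso8601 <- function(x, what, file) {
  t <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  retry <- is.na(t) & !is.na(x)
  if (any(retry)) {
    t[retry] <- as.POSIXct(strptime(x[retry], "%Y-%m-%d %H:%M:%S",
                                    tz = "UTC"))
  }
  bad <- which(is.na(t) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("%s: unparseable %s timestamp at data row(s) %s",
                 file, what, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  t
}

#' Read epoch-level sleep/wake data
#'
#' Strictly validated readers for the CSV schemas of [write_cohort()].
#' Malformed rows (unknown state codes, unparseable timestamps, missing
#' columns) abort with the offending data row numbers.
#'
#' @param path CSV file path.
#' @return `read_epochs()`: a validated tibble of epochs with parsed
#'   timestamps; `read_markers()`: a tibble of per-night markers.
#' @export
read_epochs <- function(path) {
  ep <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    night_id = readr::col_character(),
    device_id = readr::col_character(),
    epoch_start = readr::col_character(),
    epoch_len_s = readr::col_double(),
    state = readr::col_character()
  ))
  need <- c("participant_id", "night_id", "device_id", "epoch_start",
            "epoch_len_s", "state")
  missing_cols <- setdiff(need, names(ep))
  if (length(missing_cols) > 0) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!ep$state %in% c("W", "S"))
  if (length(bad) > 0) {
    stop(sprintf("%s: invalid state code(s) %s at data row(s) %s",
                 path, paste(unique(ep$state[bad]), collapse = ", "),
                 paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  ep$epoch_start <- parse_iso8601(ep$epoch_start, "epoch_start", path)
  ep
}

#' @rdname read_epochs
#' @export
read_markers <- function(path) {
  mk <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    night_id = readr::col_character(),
    bedtime = readr::col_character(),
    risetime = readr::col_character()
  ))
  need <- c("participant_id", "night_id", "bedtime", "risetime")
  missing_cols <- setdiff(need, names(mk))
  if (length(missing_cols) > 0) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  mk$bedtime <- parse_iso8601(mk$bedtime, "bedtime", path)
  mk$risetime <- parse_iso8601(mk$risetime, "risetime", path)
  mk
}

#' Assemble a cohort from epoch and marker tables
#'
#' Rebuilds a `sleep_cohort` from the tabular schema. Each night keeps one
#' series per device found for it; a device-night whose epochs are not
#' contiguous at its stated epoch length is dropped here and surfaces as a
#' `series_gap` QC flag in [derive_cohort_metrics()], as does a marker
#' night with no epochs at all.
#'
#' @param epochs Epochs tibble ([read_epochs()]).
#' @param markers Markers tibble ([read_markers()]).
#' @return A `sleep_cohort` (without latent metrics).
#' @export
assemble_cohort <- function(epochs, markers) {
  split_key <- paste(epochs$participant_id, epochs$night_id, sep = "\r")
  by_night <- split(epochs, split_key)
  series_col <- vector("list", nrow(markers))
  for (i in seq_len(nrow(markers))) {
    key <- paste(markers$participant_id[i], markers$night_id[i], sep = "\r")
    night_ep <- by_night[[key]]
    devs <- list()
    if (!is.null(night_ep)) {
      for (dev in unique(night_ep$device_id)) {
        de <- night_ep[night_ep$device_id == dev, ]
        de <- de[order(de$epoch_start), ]
        len <- de$epoch_len_s[1]
        starts <- as.numeric(de$epoch_start)
        contiguous <- length(unique(de$epoch_len_s)) == 1 &&
          (nrow(de) == 1 || all(abs(diff(starts) - len) < 1e-6))
        if (contiguous) {
          devs[[dev]] <- new_epoch_series(dev, len, de$epoch_start[1],
                                          de$state)
        }
      }
    }
    series_col[[i]] <- devs
  }
  structure(
    list(
      nights = tibble::tibble(
        participant_id = markers$participant_id,
        night_id = markers$night_id,
        bedtime = markers$bedtime,
        risetime = markers$risetime,
        series = series_col
      ),
      latent = NULL,
      config = NULL
    ),
    class = "sleep_cohort"
  )
}

#' Read a cohort directly from the two CSV artifacts
#'
#' @param epochs_path,markers_path CSV paths as written by [write_cohort()].
#' @return A `sleep_cohort`.
#' @export
read_cohort <- function(epochs_path, markers_path) {
  assemble_cohort(read_epochs(epochs_path), read_markers(markers_path))
}

#' Write / read a per-night metrics table
#'
#' `metrics.csv` columns: `participant_id`, `night_id`, `device`, `tib_h`,
#' `onset`, `offset`, `onset_latency_h`, `offset_latency_h`, `duration_h`,
#' `tst_h`; durations rounded to 4 decimals, timestamps ISO-8601.
#'
#' @param metrics Metrics tibble from [derive_cohort_metrics()].
#' @param path Output CSV path.
#' @return The path (write) or a metrics tibble (read).
#' @export
write_metrics <- function(metrics, path) {
  out <- metrics
  for (col in c("tib_h", "onset_latency_h", "offset_latency_h",
                "duration_h", "tst_h")) {
    out[[col]] <- round(out[[col]], 4)
  }
  out$onset <- iso8601(out$onset)
  out$offset <- iso8601(out$offset)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    night_id = readr::col_character(),
    device = readr::col_character(),
    .default = readr::col_character()
  ))
  m$onset <- parse_iso8601(m$onset, "onset", path)
  m$offset <- parse_iso8601(m$offset, "offset", path)
  for (col in c("tib_h", "onset_latency_h", "offset_latency_h",
                "duration_h", "tst_h")) {
    m[[col]] <- as.numeric(m[[col]])
  }
  m
}

# flatten agreement_summary() output into plain lists for JSON
agreement_to_list <- function(agr) {
  lapply(agr, function(x) {
    list(
      icc_absolute = icc_to_list(x$icc_absolute),
      icc_consistency = icc_to_list(x$icc_consistency),
      bland_altman = unclass(x$bland_altman)
    )
  })
}

icc_to_list <- function(icc) {
  list(form = icc$form, estimate = icc$estimate, ci_low = icc$ci_low,
       ci_high = icc$ci_high, conf_level = icc$conf_level,
       n = icc$n, k = icc$k, label = icc$label)
}

sensitivity_to_list <- function(sens) {
  list(
    mode = sens$mode,
    per_excluded = sens$per_excluded,
    range_duration = sens$range_duration,
    range_tst = sens$range_tst
  )
}
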