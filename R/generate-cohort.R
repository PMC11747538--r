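#' Generate a synthetic dual-device sleep cohort
#'
#' Draws, for each night, a time in bed, a test-device onset latency, a
#' linearly related reference-device latency, wake interruptions within the
#' sleep interval, and a test-device TST placed by inverting the
#' reference-on-test TST relation, then realizes both devices' nights as
#' epoch-level sleep/wake state series spanning exactly
#' `[bedtime, risetime)`. Latent (continuous, pre-quantization) per-night
#' quantities are retained and available through [latent_metrics()];
#' [derive_cohort_metrics()] recovers them from the epoch series up to one
#' epoch length per boundary.
#'
#' Generation is a pure function of the configuration: the same
#' `cohort_config` (including its seed) always yields the identical cohort,
#' and the caller's RNG state is left untouched.
#'
#' A night whose draws are infeasible (e.g. latency leaving fewer than two
#' sleep epochs) is redrawn up to 50 times, after which generation aborts
#' with a diagnostic naming the night.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `sleep_cohort`: a list with elements
#'   `nights` (tibble with columns `participant_id`, `night_id`, `bedtime`,
#'   `risetime` and a `series` list-column holding one `epoch_series` per
#'   device), `latent` (tibble of latent per-night quantities in the paired
#'   wide layout of [pair_nights()]), and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 3))
#' coh
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_nights <- allocate_nights(cfg)
  base <- as.POSIXct("2024-01-06 00:00:00", tz = "UTC")

  night_rows <- list()
  latent_rows <- list()
  day <- 0L
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("p%02d", p)
    for (j in seq_len(n_nights[p])) {
      nid <- sprintf("n%02d", j)
      day <- day + 1L
      d <- draw_night(cfg)
      if (is.null(d)) {
        stop(sprintf(
          "could not generate a feasible night for %s/%s after 50 attempts; configuration too constrained",
          pid, nid
        ), call. = FALSE)
      }
      jitter_min <- round(stats::rnorm(1, 0, 30))
      bedtime <- base + (day - 1L) * 86400 + 23 * 3600 + jitter_min * 60
      risetime <- bedtime + d$tib_min * 60

      ser_ref <- new_epoch_series(
        "ref", cfg$epoch_len_ref, bedtime,
        build_states(d$n_ref, d$on_ref, d$off_ref, d$wake_ref)
      )
      ser_test <- new_epoch_series(
        "test", cfg$epoch_len_test, bedtime,
        build_states(d$n_test, d$on_test, d$off_test, d$wake_test)
      )

      night_rows[[day]] <- tibble::tibble(
        participant_id = pid, night_id = nid,
        bedtime = bedtime, risetime = risetime,
        series = list(list(ref = ser_ref, test = ser_test))
      )
      latent_rows[[day]] <- tibble::tibble(
        participant_id = pid, night_id = nid,
        tib_h = d$tib_h,
        onset_latency_test_h = d$lat_test,
        onset_latency_ref_h = d$lat_ref,
        offset_latency_test_h = d$offlat_test,
        offset_latency_ref_h = 0,
        duration_test_h = d$tib_h - d$lat_test - d$offlat_test,
        duration_ref_h = d$tib_h - d$lat_ref,
        tst_test_h = d$tst_test,
        tst_ref_h = d$tst_ref
      )
    }
  }

  structure(
    list(
      nights = dplyr::bind_rows(night_rows),
      latent = dplyr::bind_rows(latent_rows),
      config = cfg
    ),
    class = "sleep_cohort"
  )
}

# Per-participant night counts: uniform draw on the range, then +/-1
# adjustments (still within range) until the requested cohort total is hit.
allocate_nights <- function(cfg) {
  lo <- cfg$nights_range[1]
  hi <- cfg$nights_range[2]
  n <- lo + sample.int(hi - lo + 1L, cfg$n_participants, replace = TRUE) - 1L
  if (!is.null(cfg$total_nights)) {
    while (sum(n) > cfg$total_nights) {
      cand <- which(n > lo)
      i <- cand[sample.int(length(cand), 1L)]
      n[i] <- n[i] - 1L
    }
    while (sum(n) < cfg$total_nights) {
      cand <- which(n < hi)
      i <- cand[sample.int(length(cand), 1L)]
      n[i] <- n[i] + 1L
    }
  }
  n
}

# One night's latent draws plus their epoch-grid realization. Returns NULL
# if no feasible night was found within the retry budget.
draw_night <- function(cfg, max_tries = 50L) {
  er <- cfg$epoch_len_ref
  et <- cfg$epoch_len_test
  for (try in seq_len(max_tries)) {
    tib_h <- rnorm_trunc(cfg$tib_mean, cfg$tib_sd, cfg$tib_range)
    tib_min <- round(tib_h * 60)
    tib_h <- tib_min / 60

    lat_test <- cfg$latency_min + stats::rgamma(
      1, shape = cfg$latency_shape,
      scale = (cfg$true_latency_mean - cfg$latency_min) / cfg$latency_shape
    )
    offlat_test <- if (cfg$offset_latency_mean_test > 0) {
      stats::rgamma(1, shape = 2, scale = cfg$offset_latency_mean_test / 2)
    } else 0
    lat_ref <- cfg$latency_slope_a * lat_test + cfg$latency_intercept_b +
      stats::rnorm(1, 0, cfg$noise_sd_latency)
    lat_ref <- min(max(lat_ref, 0), tib_h)

    n_ref <- as.integer(tib_min * 60 / er)
    n_test <- as.integer(tib_min * 60 / et)
    on_ref <- round(lat_ref * 3600 / er)
    on_test <- round(lat_test * 3600 / et)
    off_test <- round(offlat_test * 3600 / et)
    dur_ref_e <- n_ref - on_ref
    dur_test_e <- n_test - on_test - off_test
    if (dur_ref_e < 2 || dur_test_e < 2) next

    # reference-device wake interruptions within the sleep interval
    dur_ref_h <- dur_ref_e * er / 3600
    n_int <- stats::rpois(1, cfg$waso_rate * dur_ref_h)
    mean_len_e <- cfg$waso_mean_len * 60 / er
    wake_ref <- if (n_int > 0) {
      sum(1 + stats::rgeom(n_int, prob = 1 / mean_len_e))
    } else 0
    wake_ref <- min(wake_ref, dur_ref_e - 2L)
    tst_ref <- (dur_ref_e - wake_ref) * er / 3600

    # test-device TST by inverting the reference-on-test relation
    tst_test <- (tst_ref - cfg$tst_intercept -
                   stats::rnorm(1, 0, cfg$noise_sd_tst)) / cfg$tst_slope
    tst_test_e <- round(tst_test * 3600 / et)
    wake_test <- dur_test_e - tst_test_e
    if (tst_test_e < 1 || wake_test < 0 ||
        (wake_test > 0 && wake_test > dur_test_e - 2L)) next

    return(list(
      tib_min = tib_min, tib_h = tib_h,
      lat_test = lat_test, lat_ref = lat_ref,
      offlat_test = offlat_test,
      tst_test = tst_test, tst_ref = tst_ref,
      n_ref = n_ref, n_test = n_test,
      on_ref = on_ref, on_test = on_test,
      off_ref = 0L, off_test = off_test,
      wake_ref = as.integer(wake_ref), wake_test = as.integer(wake_test)
    ))
  }
  NULL
}

rnorm_trunc <- function(mean, sd, range) {
  if (sd == 0) {
    return(min(max(mean, range[1]), range[2]))
  }
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  stop("truncated-normal rejection sampling failed; check `tib_range`",
       call. = FALSE)
}

# n epochs: `on` leading wake, `off` trailing wake, `wake_inside` wake
# epochs placed uniformly over the interior of the sleep interval (first
# and last sleep epochs stay asleep so onset/offset are preserved).
build_states <- function(n, on, off, wake_inside) {
  st <- rep("W", n)
  lo <- on + 1L
  hi <- n - off
  st[lo:hi] <- "S"
  if (wake_inside > 0) {
    interior <- (lo + 1L):(hi - 1L)
    st[interior[sample.int(length(interior), wake_inside)]] <- "W"
  }
  st
}

#' Epoch-level sleep/wake series
#'
#' Lightweight container for one device's scored night: device id, epoch
#' length in seconds, start timestamp (the night's bedtime; epoch
#' timestamps denote epoch start, intervals are half-open), and the ordered
#' `"W"`/`"S"` state vector.
#'
#' @param device_id Device identifier.
#' @param epoch_len Epoch length in seconds.
#' @param start POSIXct start of the first epoch.
#' @param states Character vector of `"W"`/`"S"` states.
#' @return An `epoch_series` object.
#' @export
new_epoch_series <- function(device_id, epoch_len, start, states) {
  stopifnot(length(device_id) == 1, epoch_len > 0,
            inherits(start, "POSIXct"), is.character(states))
  bad <- !states %in% c("W", "S")
  if (any(bad)) {
    stop("invalid epoch states: ",
         paste(unique(states[bad]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(device_id = device_id, epoch_len = epoch_len,
         start = start, states = states),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> device %s: %d x %gs epochs from %s (%d sleep)\n",
              x$device_id, length(x$states), x$epoch_len,
              format(x$start, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
              sum(x$states == "S")))
  invisible(x)
}

#' @export
print.sleep_cohort <- function(x, ...) {
  devs <- if (nrow(x$nights) > 0) names(x$nights$series[[1]]) else character()
  cat(sprintf("<sleep_cohort> %d nights, %d participants, devices: %s\n",
              nrow(x$nights), length(unique(x$nights$participant_id)),
              paste(devs, collapse = ", ")))
  if (!is.null(x$config)) {
    cat(sprintf("  generated from cohort_config(seed = %d)\n", x$config$seed))
  }
  invisible(x)
}

#' Latent per-night quantities of a generated cohort
#'
#' Returns the continuous (pre-epoch-quantization) per-night quantities the
#' generator drew, in the paired wide layout produced by [pair_nights()].
#' These are the simulation ground truth: with noise SDs of zero the linear
#' cross-device relations hold on them exactly, whereas metrics derived
#' from the epoch series carry up to one epoch length of rounding per
#' boundary.
#'
#' @param cohort A generated `sleep_cohort`.
#' @return A tibble with one row per night.
#' @export
latent_metrics <- function(cohort) {
  stopifnot(inherits(cohort, "sleep_cohort"))
  if (is.null(cohort$latent)) {
    stop("this cohort has no latent metrics (was it read from files?)",
         call. = FALSE)
  }
  cohort$latent
}
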