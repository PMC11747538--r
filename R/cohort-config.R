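#' Configuration of the synthetic dual-device sleep cohort
#'
#' Builds and validates the generative parameters for [generate_cohort()].
#' The defaults describe a small free-living validation cohort: six
#' participants contributing 5--21 nights each (64 nights in all), a
#' 30-second-epoch reference actigraph and a 60-second-epoch test actigraph
#' worn simultaneously, with the test device overestimating sleep-onset
#' latency and underestimating total sleep time (TST) relative to the
#' reference. The cross-device error structure is linear:
#'
#' * onset latency: the test-device latency `S` is drawn from a (shifted)
#'   gamma distribution; the reference latency is
#'   `a * S + b + Normal(0, noise_sd_latency)`, clipped to `[0, TIB]`;
#' * TST: the reference TST arises from the sleep interval minus wake
#'   interruptions; the test TST is placed by inverting
#'   `ref = tst_slope * test + tst_intercept + Normal(0, noise_sd_tst)`.
#'
#' With the default coefficients (`a = 0.41`, `b = -0.26 h`,
#' `tst_slope = 0.73`, `tst_intercept = 2.15 h`) an ordinary-least-squares
#' calibration fitted to the generated cohort recovers the same form of
#' correction equations that motivated the package, and the uncalibrated
#' mean differences (test - reference) are about -0.86 h for sleep duration
#' and -0.93 h for TST.
#'
#' @param n_participants Number of participants (>= 1).
#' @param nights_range Integer range `c(low, high)` of nights per participant.
#' @param total_nights If non-`NULL`, per-participant night counts are
#'   adjusted (within `nights_range`) so the cohort totals exactly this many
#'   nights. Default 64.
#' @param epoch_len_ref,epoch_len_test Epoch lengths in seconds; must divide
#'   60 evenly (30 s reference, 60 s test by default).
#' @param tib_mean,tib_sd Mean and SD (hours) of nightly time in bed,
#'   drawn from a normal distribution truncated to `tib_range` and rounded
#'   to whole minutes.
#' @param tib_range Truncation bounds (hours) for TIB.
#' @param true_latency_mean Mean (hours) of the test-device sleep-onset
#'   latency `S`.
#' @param latency_shape Gamma shape of the latency distribution.
#' @param latency_min Lower bound (hours) of the latency distribution
#'   (`S = latency_min + Gamma(...)`); 0 by default. Setting it high enough
#'   that `a * S + b` stays positive removes the clip at zero, which is what
#'   parameter-recovery validation configurations use.
#' @param waso_rate Expected wake interruptions per hour of the sleep
#'   interval (reference device).
#' @param waso_mean_len Mean interruption length in minutes (geometric in
#'   epochs).
#' @param latency_slope_a,latency_intercept_b Cross-device latency relation:
#'   reference latency `= a * S + b` plus noise. `0 < a <= 1`.
#' @param tst_slope,tst_intercept Cross-device TST relation (reference on
#'   test). `0 < tst_slope <= 1`; intercept in hours.
#' @param noise_sd_latency,noise_sd_tst Noise SDs (hours) of the two
#'   cross-device relations. Set both to 0 for a deterministic linear
#'   cohort.
#' @param offset_latency_mean_test Mean (hours) of the small test-device
#'   sleep-offset latency (reference offset latency is 0).
#' @param seed Integer RNG seed; the cohort is a pure function of the
#'   configuration including this seed.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @seealso [generate_cohort()]
#' @examples
#' cfg <- cohort_config(seed = 7)
#' cfg$tst_slope
#' @export
cohort_config <- function(n_participants = 6L,
                          nights_range = c(5L, 21L),
                          total_nights = 64L,
                          epoch_len_ref = 30,
                          epoch_len_test = 60,
                          tib_mean = 6.5,
                          tib_sd = 0.7,
                          tib_range = c(5, 10),
                          true_latency_mean = 1.2,
                          latency_shape = 4,
                          latency_min = 0,
                          waso_rate = 0.9,
                          waso_mean_len = 5,
                          latency_slope_a = 0.41,
                          latency_intercept_b = -0.26,
                          tst_slope = 0.73,
                          tst_intercept = 2.15,
                          noise_sd_latency = 0.15,
                          noise_sd_tst = 0.25,
                          offset_latency_mean_test = 0.03,
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    nights_range = as.integer(nights_range),
    total_nights = if (is.null(total_nights)) NULL else as.integer(total_nights),
    epoch_len_ref = epoch_len_ref,
    epoch_len_test = epoch_len_test,
    tib_mean = tib_mean, tib_sd = tib_sd, tib_range = tib_range,
    true_latency_mean = true_latency_mean,
    latency_shape = latency_shape,
    latency_min = latency_min,
    waso_rate = waso_rate, waso_mean_len = waso_mean_len,
    latency_slope_a = latency_slope_a,
    latency_intercept_b = latency_intercept_b,
    tst_slope = tst_slope, tst_intercept = tst_intercept,
    noise_sd_latency = noise_sd_latency, noise_sd_tst = noise_sd_tst,
    offset_latency_mean_test = offset_latency_mean_test,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_participants < 1L) {
    stop("`n_participants` must be >= 1", call. = FALSE)
  }
  nr <- cfg$nights_range
  if (length(nr) != 2L || nr[1] < 1L || nr[2] < nr[1]) {
    stop("`nights_range` must be c(low, high) with 1 <= low <= high",
         call. = FALSE)
  }
  if (!is.null(cfg$total_nights)) {
    lo <- cfg$n_participants * nr[1]
    hi <- cfg$n_participants * nr[2]
    if (cfg$total_nights < lo || cfg$total_nights > hi) {
      stop(sprintf(
        "`total_nights` (%d) is unreachable: %d participants with %d-%d nights each span [%d, %d]",
        cfg$total_nights, cfg$n_participants, nr[1], nr[2], lo, hi
      ), call. = FALSE)
    }
  }
  for (len in c(cfg$epoch_len_ref, cfg$epoch_len_test)) {
    if (len <= 0 || 60 %% len != 0) {
      stop("epoch lengths must be positive and divide 60 s evenly",
           call. = FALSE)
    }
  }
  if (cfg$tib_mean <= 0) stop("`tib_mean` must be > 0", call. = FALSE)
  if (cfg$tib_sd < 0 || cfg$noise_sd_latency < 0 || cfg$noise_sd_tst < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (!(cfg$latency_slope_a > 0 && cfg$latency_slope_a <= 1)) {
    stop("`latency_slope_a` must be in (0, 1]", call. = FALSE)
  }
  if (!(cfg$tst_slope > 0 && cfg$tst_slope <= 1)) {
    stop("`tst_slope` must be in (0, 1]", call. = FALSE)
  }
  if (cfg$latency_min < 0 || cfg$true_latency_mean <= cfg$latency_min) {
    stop("need 0 <= `latency_min` < `true_latency_mean`", call. = FALSE)
  }
  if (cfg$waso_rate < 0 || cfg$waso_mean_len <= 0) {
    stop("`waso_rate` must be >= 0 and `waso_mean_len` > 0", call. = FALSE)
  }
  if (cfg$offset_latency_mean_test < 0) {
    stop("`offset_latency_mean_test` must be >= 0", call. = FALSE)
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d participants, %d-%d nights each%s\n",
              x$n_participants, x$nights_range[1], x$nights_range[2],
              if (is.null(x$total_nights)) ""
              else sprintf(" (total %d)", x$total_nights)))
  cat(sprintf("  epochs: ref %gs / test %gs; TIB ~ N(%g, %g) h in [%g, %g]\n",
              x$epoch_len_ref, x$epoch_len_test, x$tib_mean, x$tib_sd,
              x$tib_range[1], x$tib_range[2]))
  cat(sprintf("  latency: ref = %g*S %+g + N(0, %g); TST: ref = %g*test %+g + N(0, %g)\n",
              x$latency_slope_a, x$latency_intercept_b, x$noise_sd_latency,
              x$tst_slope, x$tst_intercept, x$noise_sd_tst))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read a cohort configuration from a YAML file
#'
#' Any field of [cohort_config()] may appear in the file; missing fields
#' keep their defaults, unknown fields are an error.
#'
#' @param path Path to a YAML (or flat `key: value`) file.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown cohort_config fields in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(cohort_config, vals)
}
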