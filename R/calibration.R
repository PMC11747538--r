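#' Calibration model for test-device sleep duration and TST
#'
#' Holds the coefficients of the two-stage linear correction of the test
#' device toward the reference device:
#'
#' * duration: `D' = min{dur_latency_coef * S + D + dur_intercept, TIB}`,
#'   where `S` is the test-device onset latency and `D` its duration — an
#'   onset-latency correction (the test device overestimates latency, so
#'   part of the latency is returned to the sleep period) plus a small
#'   bias term, clipped so a night can never sleep longer than it was in
#'   bed;
#' * TST: `T' = min{tst_slope * T + tst_intercept, D'}` — a direct linear
#'   correction clipped to the calibrated duration.
#'
#' @param dur_latency_coef Multiplier on the test-device onset latency
#'   (unitless, in `[0, 1]` for fitted models).
#' @param dur_intercept Duration intercept (hours).
#' @param tst_slope,tst_intercept TST correction slope (unitless) and
#'   intercept (hours).
#' @param provenance `"default"` for the package's built-in coefficients,
#'   `"fitted"` for models estimated from data.
#' @param diagnostics Optional list of fit diagnostics (OLS latency slope
#'   `alpha` and intercept `beta`, selected bias term, per-stage RMSE).
#' @return A `calibration_model` object.
#' @seealso [default_calibration()], [fit_calibration()]
#' @export
calibration_model <- function(dur_latency_coef, dur_intercept,
                              tst_slope = NA_real_, tst_intercept = NA_real_,
                              provenance = c("fitted", "default"),
                              diagnostics = NULL) {
  provenance <- match.arg(provenance)
  mod <- structure(
    list(dur_latency_coef = as.numeric(dur_latency_coef),
         dur_intercept = as.numeric(dur_intercept),
         tst_slope = as.numeric(tst_slope),
         tst_intercept = as.numeric(tst_intercept),
         provenance = provenance,
         diagnostics = diagnostics),
    class = "calibration_model"
  )
  validate_calibration_model(mod)
}

validate_calibration_model <- function(mod) {
  stopifnot(inherits(mod, "calibration_model"))
  if (mod$provenance == "default") {
    def <- c(0.59, 0.26, 0.73, 2.15)
    got <- c(mod$dur_latency_coef, mod$dur_intercept,
             mod$tst_slope, mod$tst_intercept)
    if (!isTRUE(all.equal(def, got, tolerance = 0))) {
      stop("a 'default' calibration model must carry exactly the built-in coefficients",
           call. = FALSE)
    }
  }
  if (mod$provenance == "fitted" &&
      (mod$dur_latency_coef < 0 || mod$dur_latency_coef > 1)) {
    stop("`dur_latency_coef` of a fitted model must lie in [0, 1]",
         call. = FALSE)
  }
  mod
}

#' Built-in default calibration
#'
#' The calibration derived in the validation study this package
#' operationalizes: `D' = min{0.59 S + D + 0.26, TIB}` and
#' `T' = min{0.73 T + 2.15, D'}` (hours).
#'
#' @return A `calibration_model` with `provenance = "default"`.
#' @examples
#' default_calibration()
#' @export
default_calibration <- function() {
  calibration_model(0.59, 0.26, 0.73, 2.15, provenance = "default")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> (%s)\n", x$provenance))
  cat(sprintf("  D' = min{%.4g*S + D %+.4g, TIB}\n",
              x$dur_latency_coef, x$dur_intercept))
  if (is.na(x$tst_slope)) {
    cat("  TST stage not fitted\n")
  } else {
    cat(sprintf("  T' = min{%.4g*T %+.4g, D'}\n",
                x$tst_slope, x$tst_intercept))
  }
  if (!is.null(x$diagnostics$bias)) {
    cat(sprintf("  latency OLS: alpha %.4g, beta %.4g; bias %.4g h\n",
                x$diagnostics$alpha, x$diagnostics$beta, x$diagnostics$bias))
  }
  invisible(x)
}

#' Fit the duration stage of the calibration
#'
#' Three steps, each deterministic given the paired nights:
#'
#' 1. Ordinary least squares of the reference onset latency on the
#'    test-device onset latency, `L_hat = alpha * S + beta`.
#' 2. Provisional correction `D* = D + (S - L_hat)` — the overestimated
#'    part of the latency is returned to the sleep period.
#' 3. Grid search of a small bias term `b` over `bias_grid` (default
#'    -5 to +5 minutes in 0.1-minute steps) maximizing the
#'    absolute-agreement ICC between `min{D* + b, TIB}` and the reference
#'    duration; ties broken toward the smallest `|b|`, then the negative
#'    candidate. The clip to TIB is inside the searched objective.
#'
#' The returned composite coefficients are `dur_latency_coef = 1 - alpha`
#' and `dur_intercept = -beta + b*`.
#'
#' @param paired Paired metrics tibble ([pair_nights()]), >= 3 nights with
#'   non-constant test-device latency.
#' @param bias_grid Candidate bias terms in hours.
#' @return A `calibration_model` with the duration stage fitted (TST stage
#'   `NA`) and diagnostics `alpha`, `beta`, `bias`, `icc_duration`,
#'   `rmse_duration`.
#' @export
fit_duration_calibration <- function(paired,
                                     bias_grid = seq(-5, 5, by = 0.1) / 60) {
  check_paired(paired, n_min = 3)
  s <- paired$onset_latency_test_h
  if (stats::var(s) == 0) {
    stop("test-device onset latencies are constant; latency OLS is unidentifiable",
         call. = FALSE)
  }
  fit <- stats::lm(onset_latency_ref_h ~ onset_latency_test_h, data = paired)
  beta <- unname(stats::coef(fit)[1])
  alpha <- unname(stats::coef(fit)[2])
  if (alpha < 0 || alpha > 1) {
    warning("latency OLS slope ", signif(alpha, 4),
            " outside [0, 1]; clamping so the correction stays a partial latency return")
    alpha <- min(max(alpha, 0), 1)
  }
  dstar <- paired$duration_test_h + (1 - alpha) * s - beta

  # deterministic search: candidates ordered by |b| then value, so the
  # first strict maximum realizes the tie-break
  grid <- bias_grid[order(abs(bias_grid), bias_grid)]
  best_b <- NA_real_
  best_icc <- -Inf
  for (b in grid) {
    cal <- pmin(dstar + b, paired$tib_h)
    icc <- tryCatch(
      icc_single(cbind(cal, paired$duration_ref_h), "absolute")$estimate,
      error = function(e) NA_real_
    )
    if (!is.na(icc) && icc > best_icc) {
      best_icc <- icc
      best_b <- b
    }
  }
  if (!is.finite(best_icc)) {
    stop("ICC undefined for every bias candidate; duration data degenerate",
         call. = FALSE)
  }
  d_cal <- pmin(dstar + best_b, paired$tib_h)
  calibration_model(
    dur_latency_coef = 1 - alpha,
    dur_intercept = -beta + best_b,
    provenance = "fitted",
    diagnostics = list(
      alpha = alpha, beta = beta, bias = best_b, icc_duration = best_icc,
      rmse_duration = sqrt(mean((d_cal - paired$duration_ref_h)^2))
    )
  )
}

#' Apply the duration calibration to one or more nights
#'
#' `D' = min{dur_latency_coef * S + D + dur_intercept, TIB}` — the result
#' can never exceed the night's time in bed.
#'
#' @param model A `calibration_model`.
#' @param onset_latency Test-device onset latency `S` (hours), vectorized.
#' @param duration Test-device sleep duration `D` (hours).
#' @param tib Time in bed (hours).
#' @return Calibrated durations (hours).
#' @examples
#' apply_duration_calibration(default_calibration(), 1, 6, 8)   # 6.85
#' apply_duration_calibration(default_calibration(), 2, 7.5, 8) # clipped to 8
#' @export
apply_duration_calibration <- function(model, onset_latency, duration, tib) {
  stopifnot(inherits(model, "calibration_model"))
  pmin(model$dur_latency_coef * onset_latency + duration + model$dur_intercept,
       tib)
}

#' Fit the TST stage of the calibration
#'
#' Ordinary least squares of the reference TST on the test-device TST.
#' The clip to the calibrated duration belongs to application
#' ([apply_tst_calibration()]), not to the fit; when calibrated durations
#' are supplied they are used only for the applied-RMSE diagnostic.
#'
#' @param paired Paired metrics tibble, >= 3 nights with non-constant
#'   test-device TST.
#' @param calibrated_durations Optional per-night calibrated durations
#'   `D'` (hours) for diagnostics.
#' @param model Optional duration-stage model to extend; a fresh model is
#'   built otherwise.
#' @return A `calibration_model` with the TST stage filled in.
#' @export
fit_tst_calibration <- function(paired, calibrated_durations = NULL,
                                model = NULL) {
  check_paired(paired, n_min = 3)
  if (stats::var(paired$tst_test_h) == 0) {
    stop("test-device TST values are constant; TST OLS is unidentifiable",
         call. = FALSE)
  }
  fit <- stats::lm(tst_ref_h ~ tst_test_h, data = paired)
  tst_intercept <- unname(stats::coef(fit)[1])
  tst_slope <- unname(stats::coef(fit)[2])
  diagnostics <- if (is.null(model)) list() else model$diagnostics
  if (!is.null(calibrated_durations)) {
    t_cal <- pmax(pmin(tst_slope * paired$tst_test_h + tst_intercept,
                       calibrated_durations), 0)
    diagnostics$rmse_tst <- sqrt(mean((t_cal - paired$tst_ref_h)^2))
  }
  calibration_model(
    dur_latency_coef = if (is.null(model)) 0 else model$dur_latency_coef,
    dur_intercept = if (is.null(model)) 0 else model$dur_intercept,
    tst_slope = tst_slope, tst_intercept = tst_intercept,
    provenance = "fitted", diagnostics = diagnostics
  )
}

#' Apply the TST calibration to one or more nights
#'
#' `T' = min{tst_slope * T + tst_intercept, D'}`, floored at 0 as a guard
#' against pathological user-supplied models.
#'
#' @param model A `calibration_model` with a fitted TST stage.
#' @param tst Test-device TST `T` (hours), vectorized.
#' @param d_prime The same nights' calibrated durations `D'` (hours).
#' @return Calibrated TST (hours), never exceeding `d_prime`.
#' @examples
#' apply_tst_calibration(default_calibration(), 5, 6.85) # 5.80
#' apply_tst_calibration(default_calibration(), 7, 6.0)  # clipped to 6.0
#' @export
apply_tst_calibration <- function(model, tst, d_prime) {
  stopifnot(inherits(model, "calibration_model"))
  if (is.na(model$tst_slope)) {
    stop("model has no fitted TST stage", call. = FALSE)
  }
  pmax(pmin(model$tst_slope * tst + model$tst_intercept, d_prime), 0)
}

#' Fit the full two-stage calibration
#'
#' Duration stage first ([fit_duration_calibration()]), then the TST stage
#' ([fit_tst_calibration()]) with the duration stage's calibrated
#' durations available for diagnostics — mirroring the equation order in
#' which the TST correction clips against the calibrated duration.
#'
#' @inheritParams fit_duration_calibration
#' @return A complete `calibration_model`.
#' @export
fit_calibration <- function(paired, bias_grid = seq(-5, 5, by = 0.1) / 60) {
  mod <- fit_duration_calibration(paired, bias_grid)
  d_cal <- apply_duration_calibration(mod, paired$onset_latency_test_h,
                                      paired$duration_test_h, paired$tib_h)
  fit_tst_calibration(paired, calibrated_durations = d_cal, model = mod)
}

#' Add calibrated columns to a paired metrics table
#'
#' @param model A complete `calibration_model`.
#' @param paired Paired metrics tibble.
#' @return `paired` with columns `duration_cal_h` and `tst_cal_h` added.
#' @export
apply_calibration <- function(model, paired) {
  check_paired(paired, n_min = 1)
  d_cal <- apply_duration_calibration(model, paired$onset_latency_test_h,
                                      paired$duration_test_h, paired$tib_h)
  paired$duration_cal_h <- d_cal
  paired$tst_cal_h <- apply_tst_calibration(model, paired$tst_test_h, d_cal)
  paired
}

check_paired <- function(paired, n_min) {
  need <- c("tib_h", "onset_latency_test_h", "onset_latency_ref_h",
            "duration_test_h", "duration_ref_h", "tst_test_h", "tst_ref_h")
  missing_cols <- setdiff(need, names(paired))
  if (length(missing_cols) > 0) {
    stop("paired table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(paired) < n_min) {
    stop(sprintf("need at least %d paired nights, got %d",
                 n_min, nrow(paired)), call. = FALSE)
  }
  invisible(paired)
}

#' Serialize / restore a calibration model
#'
#' Written as JSON with coefficients, provenance and diagnostics; a model
#' round-trips unchanged.
#'
#' @param model A `calibration_model`.
#' @param path File path (`.json`).
#' @return `write_calibration()` the path invisibly; `read_calibration()`
#'   the restored model.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(
    dur_latency_coef = x$dur_latency_coef,
    dur_intercept = x$dur_intercept,
    tst_slope = if (is.null(x$tst_slope)) NA_real_ else x$tst_slope,
    tst_intercept = if (is.null(x$tst_intercept)) NA_real_ else x$tst_intercept,
    provenance = x$provenance,
    diagnostics = x$diagnostics
  )
}
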