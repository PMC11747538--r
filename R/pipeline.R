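#' Run the full dual-device validation pipeline
#'
#' Orchestrates the whole analysis as one reproducible run: obtain a
#' cohort (generate synthetically, or read epoch/marker CSVs), derive and
#' QC per-night metrics, summarize uncalibrated agreement (both ICC forms
#' plus Bland-Altman, for sleep duration and TST), fit (or take the
#' default) two-stage calibration, summarize calibrated agreement, and run
#' the leave-one-participant-out sensitivity analysis in the requested
#' modes. Every artifact is stamped with the seed and a hash of the
#' configuration; rerunning with the same configuration reproduces the
#' same numbers.
#'
#' Artifacts written to `outdir`: `epochs.csv`/`markers.csv` (generated
#' cohorts only), `metrics.csv`, `qc_flags.csv`, `agreement.json`,
#' `calibration.json`, `calibrated_metrics.csv`,
#' `agreement_calibrated.json`, `sensitivity.json`, `report.md`,
#' `run.log`. On failure, artifacts from the aborted run are removed.
#'
#' @param outdir Output directory (created if needed).
#' @param config A [cohort_config()] for synthetic input; mutually
#'   exclusive with the CSV paths.
#' @param epochs_path,markers_path Epoch/marker CSVs for real input.
#' @param seed Optional integer overriding `config$seed`.
#' @param conf_level Confidence level for ICC intervals.
#' @param bias_grid Bias grid (hours) for the duration-stage fit.
#' @param use_default_calibration Apply the built-in default coefficients
#'   instead of fitting.
#' @param sensitivity_modes Subset of `c("fixed", "refit")`; empty vector
#'   skips the sensitivity stage.
#' @param device_test,device_ref Device identifiers.
#' @param write_plots Also write scatter and Bland-Altman PNGs (pre/post
#'   calibration).
#' @param log_level `"info"` or `"quiet"`.
#' @return Invisibly, a list with the computed objects (`cohort` paths,
#'   `metrics`, `paired`, `agreement`, `model`, `agreement_calibrated`,
#'   `sensitivity`) and `artifacts` (named file paths).
#' @export
run_pipeline <- function(outdir,
                         config = NULL,
                         epochs_path = NULL,
                         markers_path = NULL,
                         seed = NULL,
                         conf_level = 0.95,
                         bias_grid = seq(-5, 5, by = 0.1) / 60,
                         use_default_calibration = FALSE,
                         sensitivity_modes = c("fixed", "refit"),
                         device_test = "test",
                         device_ref = "ref",
                         write_plots = FALSE,
                         log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  generated <- !is.null(config)
  from_files <- !is.null(epochs_path) || !is.null(markers_path)
  if (generated == from_files) {
    stop("provide exactly one input: `config`, or both `epochs_path` and `markers_path`",
         call. = FALSE)
  }
  if (from_files && (is.null(epochs_path) || is.null(markers_path))) {
    stop("both `epochs_path` and `markers_path` are required", call. = FALSE)
  }
  if (generated && !is.null(seed)) {
    config$seed <- as.integer(seed)
    config <- validate_cohort_config(config)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  created <- character()
  art <- function(name) {
    p <- file.path(outdir, name)
    created <<- c(created, p)
    p
  }
  log_path <- art("run.log")
  logline <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (log_level == "info") message(msg)
  }

  run_meta <- list(
    seed = if (generated) config$seed else NA,
    config_hash = config_hash(if (generated) config else
      list(epochs = basename(epochs_path), markers = basename(markers_path)))
  )

  tryCatch({
    logline("run start (config hash %s)", run_meta$config_hash)

    if (generated) {
      cohort <- generate_cohort(config)
      write_cohort(cohort, art("epochs.csv"), art("markers.csv"))
      logline("generated cohort: %d nights", nrow(cohort$nights))
    } else {
      cohort <- read_cohort(epochs_path, markers_path)
      logline("read cohort: %d marker nights", nrow(cohort$nights))
    }

    metrics <- derive_cohort_metrics(cohort)
    write_metrics(metrics, art("metrics.csv"))
    readr::write_csv(qc_flags(metrics), art("qc_flags.csv"))
    paired <- pair_nights(metrics, device_test, device_ref)
    logline("derived metrics: %d valid paired nights, %d QC flags",
            nrow(paired), nrow(qc_flags(metrics)))
    if (nrow(paired) < 3) {
      stop("fewer than 3 valid paired nights after QC; cannot analyze",
           call. = FALSE)
    }

    agreement <- agreement_summary(paired, conf_level)
    write_stamped_json(c(agreement_to_list(agreement), run_meta),
                       art("agreement.json"))
    logline("uncalibrated absolute ICC: duration %.3f, TST %.3f",
            agreement$duration$icc_absolute$estimate,
            agreement$tst$icc_absolute$estimate)

    model <- if (use_default_calibration) {
      default_calibration()
    } else {
      fit_calibration(paired, bias_grid)
    }
    write_calibration(model, art("calibration.json"))
    cal <- apply_calibration(model, paired)
    write_calibrated_metrics(cal, art("calibrated_metrics.csv"))

    agreement_cal <- agreement_summary(cal, conf_level, calibrated = TRUE)
    write_stamped_json(c(agreement_to_list(agreement_cal), run_meta),
                       art("agreement_calibrated.json"))
    logline("calibrated absolute ICC: duration %.3f, TST %.3f",
            agreement_cal$duration$icc_absolute$estimate,
            agreement_cal$tst$icc_absolute$estimate)

    sens <- list()
    if (length(sensitivity_modes) > 0) {
      if (length(unique(paired$participant_id)) < 3) {
        stop("sensitivity analysis needs at least 3 participants; ",
             "rerun with sensitivity_modes = character(0) to skip it",
             call. = FALSE)
      }
      for (mode in sensitivity_modes) {
        sens[[mode]] <- leave_one_out(paired, mode, full_model = model,
                                      bias_grid = bias_grid,
                                      conf_level = conf_level)
        logline("leave-one-out (%s): duration ICC %.3f-%.3f, TST %.3f-%.3f",
                mode, sens[[mode]]$range_duration[1],
                sens[[mode]]$range_duration[2],
                sens[[mode]]$range_tst[1], sens[[mode]]$range_tst[2])
      }
      write_stamped_json(c(lapply(sens, sensitivity_to_list), run_meta),
                         art("sensitivity.json"))
    }

    if (write_plots) {
      write_pipeline_plots(paired, cal, outdir)
    }

    writeLines(
      render_report(paired, agreement, model, agreement_cal, sens, run_meta),
      art("report.md")
    )
    logline("run complete")

    invisible(list(
      metrics = metrics, paired = paired, agreement = agreement,
      model = model, calibrated = cal,
      agreement_calibrated = agreement_cal, sensitivity = sens,
      artifacts = stats::setNames(created, basename(created))
    ))
  }, error = function(e) {
    unlink(setdiff(created, log_path))
    cat(sprintf("[error] %s\n", conditionMessage(e)),
        file = log_path, append = TRUE)
    stop(e)
  })
}

config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_stamped_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", null = "null")
  invisible(path)
}

write_calibrated_metrics <- function(cal, path) {
  out <- cal
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 4)
  readr::write_csv(out, path)
  invisible(path)
}

render_report <- function(paired, agreement, model, agreement_cal, sens,
                          run_meta) {
  icc_line <- function(icc) {
    sprintf("%.2f (%d%% CI %.2f to %.2f, %s)", icc$estimate,
            round(100 * icc$conf_level), icc$ci_low, icc$ci_high, icc$label)
  }
  ba_line <- function(ba) {
    sprintf("mean %.2f h, min %.2f h, max %.2f h", ba$mean_diff,
            ba$min_diff, ba$max_diff)
  }
  block <- function(agr, title) {
    c(sprintf("## %s", title), "",
      "| measure | ICC (absolute) | ICC (consistency) | differences (test - ref) |",
      "|---|---|---|---|",
      sprintf("| sleep duration | %s | %s | %s |",
              icc_line(agr$duration$icc_absolute),
              icc_line(agr$duration$icc_consistency),
              ba_line(agr$duration$bland_altman)),
      sprintf("| TST | %s | %s | %s |",
              icc_line(agr$tst$icc_absolute),
              icc_line(agr$tst$icc_consistency),
              ba_line(agr$tst$bland_altman)),
      "")
  }
  out <- c(
    "# Dual-device sleep validation report", "",
    sprintf("%d paired nights, %d participants; seed %s; config hash %s.",
            nrow(paired), length(unique(paired$participant_id)),
            run_meta$seed, run_meta$config_hash), "",
    block(agreement, "Measurements (uncalibrated)"),
    "## Calibration", "",
    sprintf("`D' = min{%.4g*S + D %+.4g, TIB}`; `T' = min{%.4g*T %+.4g, D'}` (%s).",
            model$dur_latency_coef, model$dur_intercept,
            model$tst_slope, model$tst_intercept, model$provenance), "",
    block(agreement_cal, "Measurements (calibrated)")
  )
  if (length(sens) > 0) {
    out <- c(out, "## Sensitivity (leave one participant out)", "")
    for (mode in names(sens)) {
      s <- sens[[mode]]
      out <- c(out, sprintf(
        "- %s calibration: duration ICC %.2f-%.2f, TST ICC %.2f-%.2f",
        mode, s$range_duration[1], s$range_duration[2],
        s$range_tst[1], s$range_tst[2]))
    }
    out <- c(out, "")
  }
  out
}

write_pipeline_plots <- function(paired, cal, outdir) {
  specs <- list(
    list(cal = FALSE, data = paired, m = "duration"),
    list(cal = FALSE, data = paired, m = "tst"),
    list(cal = TRUE, data = cal, m = "duration"),
    list(cal = TRUE, data = cal, m = "tst")
  )
  for (s in specs) {
    tag <- paste0(s$m, if (s$cal) "_calibrated" else "_uncalibrated")
    ggplot2::ggsave(
      file.path(outdir, paste0("scatter_", tag, ".png")),
      plot_device_scatter(s$data, s$m, calibrated = s$cal),
      width = 5, height = 5, dpi = 120
    )
    ggplot2::ggsave(
      file.path(outdir, paste0("bland_altman_", tag, ".png")),
      plot_bland_altman(s$data, s$m, calibrated = s$cal),
      width = 5, height = 5, dpi = 120
    )
  }
}
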