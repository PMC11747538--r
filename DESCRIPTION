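Package: sleepcal
Title: Agreement Statistics and Calibration for Dual-Device Actigraphy Sleep Measures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Derives per-night sleep summaries (time in bed, onset and offset
    latencies, sleep duration, total sleep time) from epoch-level sleep/wake
    series scored by two wrist actigraphs worn simultaneously, quantifies
    inter-device agreement with two-way single-measurement intraclass
    correlation coefficients (absolute agreement and consistency, with
    F-based 95 percent confidence intervals) and Bland-Altman difference
    summaries, fits and applies a two-stage linear calibration of the test
    device toward the reference device (onset-latency correction with an
    ICC-optimizing bias term for sleep duration; direct linear correction
    for total sleep time, both with physical clipping), and assesses
    robustness by leave-one-participant-out sensitivity analysis. Includes a
    seeded synthetic-cohort generator that emulates the dual-device error
    structure so the whole pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
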