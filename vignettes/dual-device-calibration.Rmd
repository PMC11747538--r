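---
title: "Validating and calibrating a test actigraph against a reference device"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and calibrating a test actigraph against a reference device}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepcal)
```

`sleepcal` operationalizes a free-living device-validation design: two
wrist actigraphs worn simultaneously over many nights, participants
marking bedtime and risetime, and per-night sleep summaries compared
between the devices. This vignette documents the statistical model, the
tunable parameters, the synthetic-data generator, and the design choices
made where more than one defensible convention exists.

## Per-night metrics and their conventions

Each device contributes, per night, an ordered sleep/wake state series
at a fixed epoch length (30 s for the reference device, 60 s for the
test device by default). Epoch timestamps denote epoch *start*, and
epochs are half-open intervals `[start, start + len)`. From a series and
the markers we derive, all in hours:

* TIB (time in bed) = risetime − bedtime;
* sleep onset = start of the first sleep epoch at/after bedtime;
* sleep offset = *end boundary* of the last sleep epoch before risetime;
* onset latency `S`, offset latency, duration `D` = offset − onset,
  and TST `T` = total sleep-epoch time within `[onset, offset)`.

Three conventions are deliberate rather than inherited:

* **Offset is an end boundary.** "One minute after the final sleep" is
  exact for a minute-resolution device; at 30 s epochs the analogous
  quantity is the epoch's end (+30 s), keeping the definition
  epoch-length-invariant (metrics are unchanged when every epoch is
  split in half — a property the tests enforce).
* **Epochs straddling a marker** belong to the night iff their start
  lies in `[bedtime, risetime)`; the series must cover that window
  exactly, else the night is QC-flagged (`series_gap`).
* **The same counting rule is applied to both devices.** Vendor scoring
  software computes TST internally for real devices; here both devices'
  already-scored series pass through the identical epoch-counting rule,
  which matches the stated definitions of the summaries.

The partition identity `TIB = S + D + offset latency` then holds exactly
at epoch resolution, and `0 ≤ T ≤ D ≤ TIB` always. Nights failing QC
(no sleep epoch, missing/misordered markers, series gaps) are excluded
from every downstream stage and reported as flags.

## Agreement model

Nights are pooled across participants into an n × 2 ratings matrix (one
row per night, one column per device) and summarized by two-way
single-measurement ICCs. With MSR, MSC, MSE the between-row,
between-column and residual mean squares of the two-way crossed
decomposition without replication:

* consistency: ICC(C,1) = (MSR − MSE) / (MSR + (k−1) MSE);
* absolute agreement: ICC(A,1) = (MSR − MSE) /
  (MSR + (k−1) MSE + (k/n)(MSC − MSE)).

Confidence intervals follow the standard conventions for these forms:
the exact F ratio MSR/MSE on (n−1, (n−1)(k−1)) df for consistency, and
the Satterthwaite-approximated F interval for absolute agreement. The
latter is what produces the characteristic *negative* lower bounds when
a large systematic offset coexists with good relative tracking; both are
pinned against an independent reference implementation on shared
fixtures in the test suite. Bland–Altman summaries (mean, extremes, SD,
±1.96 SD limits of agreement) use the fixed project-wide sign convention
test − reference. Qualitative labels use the usual bands: < 0.5 poor,
0.5–0.75 moderate, 0.75–0.9 good, ≥ 0.9 excellent.

Pooling nights ignores within-participant clustering. That mirrors the
validation design this package operationalizes and is a documented
limitation, not a bug: a hierarchical ICC would answer a different
question. The leave-one-participant-out analysis is the pragmatic check
that pooling does not let one participant drive the result.

## Two-stage calibration

Test devices of this class overestimate onset latency (movement-quiet
wake scored as wake for longer before sleep is detected) while their
offset latencies are nearly unbiased; and they underestimate TST. The
calibration reflects that structure:

1. **Duration, via latency.** OLS of reference latency on test latency,
   `L̂ = αS + β`; the provisional correction returns the overestimated
   latency to the sleep period, `D* = D + (S − L̂)`. A bias term `b`,
   searched over ±5 minutes in 0.1-minute steps, absorbs the small
   offset-latency bias; it is selected to maximize the
   absolute-agreement ICC of `min{D* + b, TIB}` against the reference
   duration, with the clip *inside* the searched objective so the
   optimizer sees the final equation. Ties break toward the smallest
   |b|, then the negative candidate — a deterministic search. The
   composite model is `D' = min{(1−α)S + D + (−β + b), TIB}`.
2. **TST, directly.** OLS of reference TST on test TST, applied as
   `T' = min{slope·T + intercept, D'}`, with an explicit floor at 0
   guarding against pathological user-supplied models. Duration is
   calibrated before TST because `T'` clips against `D'`.

Choices worth making explicit: the regression direction is
reference-on-test (the test device is being calibrated *toward* the
reference); the bias grid is symmetric (±5 min) since only an upper
magnitude is implied by the design; the TST fit includes all nights
(clipped or not — exclusion would condition on the fit itself); fitted
`dur_latency_coef` is clamped to [0, 1] with a warning, since a latency
correction cannot exceed the latency; and only the composite intercept
is a model coefficient — the decomposition into −β and b is kept in the
diagnostics. The built-in `default_calibration()` carries the fixed
coefficients 0.59, 0.26, 0.73, 2.15 (hours).

## The synthetic cohort generator

The generator exists so every stage is testable at the study's design
size without device recordings. Per night it draws TIB ~ Normal(6.5 h,
0.7 h) truncated to [5, 10] h and rounded to whole minutes (so both
epoch grids divide it evenly); a test-device latency `S` from a gamma
distribution (shape 4, mean 1.2 h, optional lower shift); a reference
latency `a·S + b + Normal(0, σ_lat)` clipped to [0, TIB] with defaults
a = 0.41, b = −0.26 h — the algebraic inversion of the default duration
correction; wake interruptions in the reference sleep interval as a
Poisson count (0.9 per hour of sleep) of geometric-length runs (mean
5 min), giving the reference TST; and a test TST placed by inverting
`T_ref = 0.73·T_test + 2.15 + Normal(0, σ_tst)`. Everything is then
realized as epoch state sequences (latent times rounded to the epoch
grid, matching how scored data arise), with infeasible draws redrawn up
to 50 times before aborting with a diagnostic.

Defaults were set once, by simulation, so that the default cohort
reproduces the error structure such validation studies report:
uncalibrated mean differences near −0.86 h (duration) and −0.93 h
(TST), reference sleep durations averaging ~6.2 h, test offset latency
mean 0.03 h, moderate uncalibrated absolute ICCs with much higher
consistency ICCs, and 6 participants × 64 nights (per-participant counts
drawn uniformly on 5–21, then nudged within range to hit the total).
The noise SDs (σ_lat = 0.15 h, σ_tst = 0.25 h) are not independently
documented quantities; they are the package's chosen stand-ins, as are
the TIB and latency distributions.

Two generator subtleties matter for validation work:

* **Latent truth vs. epoch realization.** Epoch quantization perturbs
  every derived metric by up to one epoch per boundary, so exact linear
  relations cannot survive the epoch grid. The generator therefore
  retains the continuous latent quantities (`latent_metrics()`):
  zero-noise parameter recovery is exact (to numerical tolerance) on
  latent metrics, while recovery through the full epoch pipeline is
  asserted at realistic tolerances.
* **The clip at zero is structural.** With the default latency
  distribution, a·S + b is negative for an appreciable share of nights
  and the reference latency clips at 0; that is realistic (reference
  latencies are often zero) but biases OLS recovery of (a, b)
  regardless of noise. Parameter-recovery validation therefore uses a
  shifted latency distribution (`latency_min = 0.8 h`, mean 1.5 h) that
  keeps the relation unclipped; the default cohort keeps the clip.
* **WASO placement.** Interruption count × run length determines each
  night's wake total; the wake epochs are then placed uniformly at
  random over the interior of the sleep interval, since every per-night
  summary depends only on the totals. Run adjacency is not preserved —
  analyses of sleep fragmentation *structure* are out of scope.

What passing tests on synthetic cohorts do **not** show: that real
devices have linear, homoscedastic cross-device relations; that real
WASO is Poisson-geometric; that participants are exchangeable; or that
the scored series themselves are accurate (the upstream
activity-count-to-sleep scoring algorithm is consumed, not modeled —
naps, split nights and circadian structure are likewise out of scope).

## Numerical and degenerate-input conventions

All durations are carried internally as hours (doubles); CSV output is
rounded to 4 decimals. ICCs require n ≥ 3 rows (mean squares are
degenerate below that for CI purposes). Identical columns give estimate
1 with CI (1, 1); an all-constant matrix is an error. The bias grid
search skips candidates where the ICC is undefined and errors only if
every candidate fails. Leave-one-out subsets too small to fit are
reported as undefined entries with diagnostics and a warning, excluded
from ranges, never silently dropped. The pipeline aborts (removing
partial artifacts) with fewer than 3 valid paired nights after QC, and
names the sensitivity stage when fewer than 3 participants are present.

## Problem sizes and determinism

The test suite validates at the study's own scale: 64-night cohorts for
agreement and calibration properties, 100 seeds for the
calibration-improves-agreement property, 500 replicates for CI coverage
at a known ICC of 0.7, 1,000-night fuzzed cohorts for the clipping
contracts, and a 640-night cohort for coefficient-recovery convergence.
Every stochastic step flows from a single integer seed: the generator is
a pure function of its configuration, the caller's RNG state is never
disturbed, and rerunning the pipeline with the same configuration
reproduces its JSON artifacts byte for byte.
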