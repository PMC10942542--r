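---
title: "Methods: the attention-weighted timing-report model and its pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the attention-weighted timing-report model and its pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockbind)
```

`clockbind` analyses temporal-binding experiments in which event times are
reported as positions of a rotating clock hand while visuospatial
attention is measured concurrently with near-threshold visual probes. This
vignette explains the model the package implements, the conventions and
numerical choices it commits to, what its synthetic-data generator does and
does not emulate, and the known limitations.

## Clock geometry

The clock hand sweeps one revolution in 1800 ms by default, so 1 degree of
arc equals 5 ms; `clock_config()` carries the conversion and every angle
column is degrees, clockwise, in `[0, 360)`. Zero degrees is defined *per
trial* as the hand position at the judged event, which is why the analysis
never needs the screen's 12-o'clock orientation.

A timing-report error is the angular difference between reported and actual
hand position, wrapped into `(-180, 180]` degrees before conversion to
milliseconds. The wrap convention is a package commitment, not an empirical
fact: a report nearly a full revolution away is inherently ambiguous, and
minimal-magnitude wrapping is the only reading consistent with errors on
the order of ±100 ms. The single ambiguous point — an exactly antipodal
report — is signed positive (+900 ms at the default speed). This matters
only in pathological data; real report errors concentrate well inside the
branch point.

## The attention-weighted timing-report model

The model predicts a participant's timing report from their probe detection
rates alone. Each probe location `k` corresponds to a report time `T_k`:
for the sound-time (outcome) task, locations −50° … +50° map to −250 … +250
ms with the sound at 0 ms; for the keypress-time (action) task, the same
window maps to 0 … 500 ms because the keypress — one 250 ms action–sound
delay before the sound — is the temporal origin. Rates are min-corrected,
`D'_k = D_k − min(D)`, and the prediction is the weighted mean
`sum(T_k D'_k) / sum(D'_k)`.

Three structural consequences are worth naming, and the test suite pins
each one:

* **Affine invariance.** Min-subtraction removes any additive shift in the
  rates and normalisation removes any positive scaling, so uniform
  false-alarm floors and lapse compression cancel out of the prediction.
* **Bounds and delta profiles.** The prediction always lies in
  `[min T, max T]` and hits a grid point exactly iff the corrected profile
  is a delta there. Ties at the minimum all receive weight zero, a direct
  consequence of the correction.
* **Degenerate profiles.** A perfectly flat profile has no information; the
  package falls back to uniform weights (the limit of adding equal mass
  everywhere), returns the grid mean, and flags `fallback_used`. On the
  symmetric outcome grid the fallback is 0 ms.

The rates are used as weights exactly as measured — no smoothing, no
continuity correction. The mapping from detection rate to "amount of
attention" is not calibrated (is 0.5 vs 0.2 the same attentional difference
as 0.8 vs 0.5?); the model therefore claims proportionality to the actual
report, not equality, and the pipeline's headline statistics are rank
correlations between modeled and actual quantities.

## Preprocessing and participant screening

Screening is two-staged and ordered:

1. **False-alarm rate** — detections on catch trials, pooled over
   conditions (the pooling is a package choice; per-condition rates are
   recoverable from the trial table). Participants above 0.5 are removed.
   The threshold is configurable; 0.5 separates catastrophic responders
   (rates of 0.6–1.0) from typical retained rates (< 0.1) with a wide
   margin on either side.
2. **MAD–median rule** — applied to the per-condition median and SD of the
   timing-report error across the remaining participants, flagging `p` when
   `0.6745 |p − median(P)| > 3 MAD`, with MAD the *unscaled* median
   absolute deviation. The inequality is implemented literally in this
   printed form; the algebraically equivalent "robust z > 2.24" form is
   not used, so the constant 3 is preserved as stated. A participant
   flagged on any of the four statistics (median and SD in each of two
   conditions) is excluded — the union is the conservative reading when
   the handling is not further specified.

The MAD reference statistics are computed once, on the post-stage-1 cohort,
and are attached to the result; re-applying the rule to the surviving
cohort with that stored reference changes nothing, which makes the
procedure idempotent and auditable. Recomputing the reference on a shrunken
cohort would instead chase its own tail.

Binding effects are differences of per-participant condition medians with
the field's sign conventions — outcome binding SO − AS (or VS − AS), action
binding AS − AO — so the classic effects are positive. Medians of an even
number of trials are midpoints of the central order statistics.

## The synthetic experiment generator

The generator exists so every pipeline stage can be exercised, and
parameter recovery tested, without an empirical dataset. Per participant
and condition it emits exactly the designed trial counts in random order.
The four shipped presets encode the study designs: 280 trials/condition
(50 timing + 50 catch + 30 × 6 probe) for the two standard outcome
experiments, 170 (30 + 20 + 20 × 6) for the attention-matched variant, and
480 (50 + 100 + 30 × 11) for the action-binding design, all with a 250 ms
action–sound delay and the 1800 ms clock.

**Attention fields.** Each condition's detection-rate profile is a
max-normalised product of a rising and a falling logistic, parameterised by
baseline, peak amplitude, peak location, and the two slopes. Defaults are
chosen once to reproduce the qualitative shapes of the empirical profiles:
SO low before the sound and high after; AS (and its vibrotactile stand-in
VS) elevated from the keypress, peaking just before the sound, falling
sharply after; in the action task both conditions peak right after the
keypress, with the AS field decaying more slowly because the sound re-cues
attention. Probe detections are Bernoulli draws from
`fa + (1 − fa − lapse)·A(x)` (defaults: false alarm 0.04, lapse 0.02,
matching typical retained false-alarm rates of a few percent).

**Timing reports.** The default generator is model-consistent: a
participant's reports are the attention-weighted model applied to *their
own realized detection profile*, plus Gaussian noise (default SD 60 ms, a
typical trial-to-trial spread for clock-method reports). Basing reports on
the realized profile rather than the shared true field gives participants
genuine between-subject variation that the analyst's modeled report can
track — with a shared field the modeled–actual correlation would be
structurally zero and parameter recovery meaningless. `report_basis =
"field"` and a `"shift"` generator (true time plus a constant) are provided
for robustness checks. `plant_binding()` retunes one field's peak location
by root-finding so the modeled difference between two conditions equals a
target within 1 ms, giving recovery tests a known ground truth.

**What the generator does not emulate**: response-time dynamics of the
voluntary keypress (the event angle is simply uniform), eye movements and
their gating, screen geometry, perceptual learning or drift across trials,
and any genuine timing-judgment component beyond the attention model plus
noise. Passing recovery tests therefore shows the pipeline is a consistent
estimator of the generator's world, not that the attention model is true of
real observers.

**Seeding.** One master seed; participant `i` uses `seed + i`, so any
participant subset reproduces exactly and the same call is byte-identical
on disk.

**Staircase.** The threshold procedure runs two interleaved 2-down-1-up
lines from intensities 128 (background) and 200, each to 15 reversals,
clamped to [128, 255]. The step schedule — start 8, halved after each of
the first three reversals per line, floor 2 — and the threshold estimate —
mean of the last 10 reversal intensities per line — are standard adaptive
practice; the source procedure's citation-level details are not stated, so
these are package defaults, and threshold estimates are only simulator
inputs. The rule converges on the 70.7% detection point; the test suite
checks the median estimate over 500 runs lands within one initial step of a
simulated observer's true 70.7% point. A degenerate observer who detects
everything never produces a direction change, so runs are capped
(`max_trials`) and return partial results with a warning.

## Inferential toolkit choices

* **t tests.** Unpaired tests default to pooled variance because the
  reported degrees of freedom follow `n1 + n2 − 2`; Welch is a flag.
  Effect sizes are `dz = t/sqrt(n)` (paired) and
  `ds = t·sqrt(1/n1 + 1/n2)` (pooled). Zero-variance contrasts raise
  errors from the standalone functions; the pipeline catches the
  degenerate case and reports it as undefined rather than failing a whole
  run.
* **Power** is exact noncentral-t: noncentrality `dz·sqrt(n)`, `n − 1` df,
  both rejection regions counted when two-tailed.
* **JZS Bayes factors** integrate the noncentral-t likelihood against a
  Cauchy(0, √2/2) prior on the standardized effect; directional variants
  truncate and renormalise the prior, so `BF+0 + BF−0 = 2·BF10` — an
  identity the tests verify numerically, alongside an independent
  g-representation (inverse-gamma mixture) oracle. The quadrature splits at
  zero and falls back to a finite integration range when a negligible-mass
  tail defeats the adaptive rule.
* **Spearman correlations** use midranks. The one-tailed p is an exact
  full-enumeration permutation p up to n = 9 (~3.6 × 10^5 orderings —
  beyond that enumeration in R costs minutes for no practical gain) and
  the t approximation above. Constant inputs are an error, not rho = 0.
* **Box-plot rule.** Bivariate outliers are points outside per-coordinate
  Tukey fences (quartile ± 1.5 IQR, default quantile definition). The
  cited bivariate variants (bagplots) are not implemented; the fence
  multiplier is configurable. Correlations are always reported both with
  and without the removal.
* **FDR** is Benjamini–Hochberg step-up via `p.adjust`. Note the step-up
  transform is not idempotent on its own output in general; the tests pin
  the arithmetic against an independent oracle instead of asserting
  idempotence.
* **Repeated-measures ANOVA** fits `Error(participant/(A*B))` strata via
  `aov`; partial eta squared is `SS_effect/(SS_effect + SS_error)` within
  each effect's own stratum. Uncorrected F is the default (the reported
  analyses do not state a sphericity correction); Greenhouse–Geisser is
  available, with epsilon from orthonormal contrasts of the participant ×
  cell matrix. Replicate rows within a cell are averaged before fitting.

## Numerical and degenerate-input choices

* Flat detection profiles: uniform-weight fallback, flagged.
* Antipodal report errors: signed +900 ms (tie toward positive).
* Exclusions with an empty surviving cohort: error, never silent.
* `run_analysis()` with sampling noise off (deterministic probe counts,
  zero report noise) reproduces modeled = actual binding exactly, and the
  resulting zero-variance correlation and contrast are reported as
  undefined — not as a spurious perfect result.

## Known limitations

* Recovery of a planted modeled binding is mildly biased towards zero
  (≈ 12% at 20–30 probe trials per location): the minimum of a sampled
  profile is an extreme-value statistic, so `D − min(D)` systematically
  overcorrects. The bias shrinks with probe count; it is a property of the
  estimator itself, not of the simulation.
* Attention is modeled (and, in the design being emulated, measured) only
  on the probed 100-degree window, one time point per location; whatever
  attention does outside that window is invisible to the model.
* Detection rate is an uncalibrated proxy for attention; the model's
  claims are ordinal, hence the rank-correlation framing.
* The ANOVA inclusion Bayes factors and Kendall-based correlation Bayes
  factors of the original analyses are out of scope.

## Problem sizes used by the test suite

The suite simulates at deliberately modest sizes chosen to make each check
informative: exhaustive model-oracle grids at 3 levels per location (729
profiles) plus 1,000 random 11-level profiles; 500 staircase runs for the
convergence property; 5,000 null datasets (n = 18) for type-I calibration;
and a 40-participant full-design recovery run for the planted 100 ms
binding. These sizes are the package's own verification choices and are
stated here so they can be scaled up when stronger evidence is wanted.
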