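---
title: "Early intraoperative hypotension prediction from ABP waveforms: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early intraoperative hypotension prediction from ABP waveforms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(iohpredict)
```

# The problem

Intraoperative hypotension (IOH) — a sustained drop of mean arterial
pressure (MAP) below 65 mmHg for at least one minute — is associated with
organ injury, and anesthesiologists would like a warning a few minutes
before an episode begins. `iohpredict` implements a complete, testable
pipeline for this task on continuous arterial blood pressure (ABP)
waveforms sampled at 125 Hz: signal quality control, event detection and
burden quantification, a stochastic data-point framing scheme with a
forward-looking prediction horizon, two predictors (a MAP-threshold rule
and a 1-D convolutional network), and a patient-grouped evaluation
framework designed around generalizability questions.

Because real intraoperative waveform repositories cannot be shipped with a
package, the pipeline is exercised end to end on a synthetic ABP generator
with exact ground truth. The generator is first-class, tested code: every
downstream module is validated against the generator's scripted truth, and
all study-scale experiments in the test suite run on simulated cohorts.

# The synthetic generator

Each simulated patient is built from the MAP trajectory outward:

* **MAP trajectory** (1 Hz): a baseline (default 80 mmHg) plus a Gaussian
  random walk with configurable scale in mmHg per square-root minute,
  plus hypotensive dips — rectangular excursions of 15–30 mmHg lasting
  1.5–4 minutes, with a 10 s linear on/off ramp, scheduled by a Poisson
  process (or scripted exactly). Sub-minute transients and Gray-Zone
  plateaus arise naturally from the drift.
* **Beat schedule**: instantaneous heart rate is a baseline (70 bpm) plus
  a slow 5-minute sinusoid (±3 bpm) and per-beat white jitter; beat onsets
  integrate this rate.
* **Pulse morphology**: every beat is a fixed two-bump template (systolic
  upstroke plus dicrotic bump), rescaled per beat so the sampled mean of
  the beat equals the scripted MAP at the beat midpoint and the
  peak-to-trough range equals the configured pulse pressure (50 mmHg).
  This preserves the property the prediction task depends on: the segment
  mean tracks MAP exactly.
* **Artifacts**: square waves railing outside the physiologic range (as
  from a fast-flush test), broadband noise, flatlines, and spikes,
  injected over recorded intervals so that the quality-control modules can
  be scored against exact artifact truth.

`simulate_cohort()` steers the class separation of the downstream labeled
dataset (ΔMean, defined below): half the cohort is made dip-prone with a
lowered baseline, half stable with a raised baseline and no dips. The
baseline split is `1.58 × target` — the constant maps the requested ΔMean
to the realized one, accounting for the fact that negatives arise from
both groups while positives arise almost exclusively from the prone group.
It was calibrated once against the generator's own contract (targets of 6
and 12 mmHg across several seeds, realized within ±0.5 mmHg) and frozen.

What the generator does **not** emulate: baroreflex and drug
pharmacodynamics, respiratory modulation, beat-morphology variability,
measurement drift, or cuff recalibrations. Passing tests therefore
demonstrate the correctness of the pipeline's mechanics — labeling,
leakage control, metric arithmetic, steering — not clinical performance on
real hemodynamics.

# Preprocessing

Ingest accepts any sampling rate at or above the canonical 125 Hz;
`resample_to_125()` uses Fourier-domain resampling (spectrum truncation),
so content below the 62.5 Hz output Nyquist is preserved. Upsampling is
refused rather than fabricated.

`detect_beats()` follows the Gaussian-derivative / Shannon-energy
envelogram family: convolution with a first-derivative-of-Gaussian kernel
(σ = 0.1 s), rectification (upstrokes only), normalization by a robust
maximum (99.5th percentile — one artifact cannot rescale the record),
Shannon energy `−x²·log x²` floored at 1e−12, a 0.12 s moving-average
envelope, and peak picking with a 0.3 s refractory period. Candidate
envelope peaks must coincide with a strong upstroke (half the 95th
percentile of the rectified derivative), which suppresses dicrotic bumps.
The systolic peak is the raw maximum just after the strongest local
upstroke; the beat onset is the preceding trough. Records are
reflect-padded so edge beats keep their upstroke energy. All parameters
are exposed in `beat_detector_params()`. On artifact-free synthetic
records the detector's recall and precision against scripted beat truth
exceed 0.99 and systolic peak times are sample-exact.

Beat-level quality control (`flag_abnormal_beats()`) applies a classical
signal-abnormality-index rule set: plausible SBP/DBP/MAP ranges, minimum
pulse pressure, plausible period, beat-to-beat SBP and period jumps, and a
within-beat flatline variance floor. The exact thresholds of the rule sets
used by clinical monitors vary between reports; the defaults here
(`abnormality_rules()`) are standard values and every threshold is
configurable. A patient enters the analysis only if valid beats cover at
least 90% of the record (`clean_fraction()`).

The 1 Hz MAP series interpolates per-beat MAP linearly between valid
beats, anchored at beat onsets; seconds farther than 5 s from any valid
beat are masked invalid and never used in statistics. Because the series
is a 1 Hz reconstruction, a detected event onset can differ from the
scripted truth by one second; the test suite accounts for exactly this
quantization and nothing else.

# Events and burden

`detect_events()` finds maximal runs of consecutive valid seconds with
MAP < 65 mmHg lasting at least 60 s. Invalid seconds break runs — the
conservative choice: hypotension is never asserted across missing data.
There is no gap merging by default (a configurable merge gap exists for
sensitivity analyses). `severity_summary()` reports event counts and
durations, the fraction of valid time below threshold, the area under
threshold (AUT, mmHg·min) accumulated over **all** sub-threshold seconds
including sub-minute transients, and the time-weighted average
TWA = AUT / duration. Both equal brute-force per-second accumulation
exactly, by construction and by property test.

# Data-point framing and labeling

Candidate prediction times advance by exponential inter-sample intervals
(mean 3 minutes, i.e. rate 1/3 per minute) clipped to a 3-minute cap; a
configurable floor exists as well (default 0 — the cap prevents long
sampling gaps, and both bounds are exposed because reasonable readings of
"capped" differ). Each candidate `t_now` anchors three consecutive
half-open windows:

* **Observation window** `[t_now, t_now+80)` — the first minute certifies
  a hypotension-free baseline; the final 20 s, `[t_now+60, t_now+80)`,
  are the model input (2500 samples at 125 Hz).
* **Prediction window** `[t_now+80, t_now+380)` — an event **onset** here
  makes the point positive (anchored to the earliest such onset).
* **Slack window** `[t_now+380, t_now+440)` — an onset here voids the
  point: calling it negative would penalize a model for alarming slightly
  early.

A point is skipped when an event interval intersects the observation
window (the signal already shows hypotension), and labeled negative only
when no onset falls anywhere in the frame. Segment extraction additionally
requires 95% of the extraction zone to be covered by valid beats,
otherwise the point is skipped as poor quality. Every candidate maps to
exactly one of the five outcomes; skip reasons are tallied in the dataset
provenance.

ΔMean — the mean segment-MAP of negatives minus positives — measures the
class separation of the resulting dataset. The literature reports both
segment-based and event-minute-based variants with very different values;
this package uses the segment-based definition throughout
(`delta_mean()`).

Positive-class augmentation shifts `t_now` backward by small offsets
(default −10 and −5 s) and re-runs the full decision procedure on the
shifted candidate, keeping only shifts that re-label positive and pass the
quality rule. Augmentation therefore cannot create leakage, and augmented
points inherit their parent's patient identity so folds stay
patient-grouped.

# Predictors

**MAP-threshold baseline.** The mean MAP of the 20 s segment is compared
to a threshold; at or below the threshold alarms (ties alarm — the
conservative side). In score mode the negated mean MAP is a continuous
risk score whose ROC equals the explicit 55–85 mmHg threshold sweep
extended over the observed range.

**1-D CNN.** Seven valid-padding convolution blocks (kernel 10; channels
32, 32, 64, 64, 128, 128, 128), each followed by batch normalization,
ReLU, stride-2 max pooling, and dropout (rate 0.01), then global average
pooling, a 64-unit ReLU dense layer, and a sigmoid output. Inputs are
scaled by the fixed affine map `(x − 80)/40` rather than per-segment
normalization — z-scoring each segment would erase the absolute MAP level,
which is the dominant signal. Published descriptions of this architecture
family leave channel widths, pooling, and the head unspecified; the
defaults above are conventional and all are exposed in `cnn_spec()`.
A stacked "double ReLU" collapses to a single ReLU and is implemented as
one. Training uses weighted binary cross-entropy with class-balanced
weights `n_total/(2 n_c)`, Adam at learning rate 0.001, batch size 20, up
to 150 epochs, and early stopping on validation AUC-ROC with patience 10;
the weights of the best-validation epoch are kept. The engine is written
as im2col patch matrices times weight matrices so all heavy arithmetic is
BLAS; with a fixed seed and single-threaded BLAS runs are deterministic.

# Evaluation framework

Folds are patient-grouped (a patient's points never straddle a split) and
prevalence-stratified: patients ordered by their positive-point fraction
are dealt round-robin into five test groups (~20% each); the validation
set (~10%) is a systematic draw from the prevalence-ordered remainder, the
rest trains. The operating point fixes specificity at 80%: the threshold
is the smallest observed score with at least 80% of negatives below it,
selected on the evaluated score set itself — the only reading consistent
with a reported specificity of exactly 80% in every fold (a
validation-selected mode would generalize the threshold but cannot
reproduce that). Point metrics, AUC-ROC (tie-corrected trapezoid), AUC-PR
(step integration), Brier score and 10-bin calibration curves are
reported per fold and aggregated as mean ± 1.96·sd/√k.

Cross-dataset experiments train on one cohort (with an internal
patient-grouped validation split) and test on another; diagonal cells use
within-cohort cross-validation. ΔMean standardization makes such
comparisons fair: data points are binned by segment MAP (2.5 mmHg bins);
positives are all retained and per-bin negative quotas are reweighted by a
one-parameter exponential tilt over bin index, with the parameter found by
bisection so the resampled negative mean lands at
`mean(positives) + target`. The published description of this procedure —
equal samples per bin per class — by itself forces ΔMean toward zero, yet
a controlled nonzero value (5.01 mmHg) is the quantity of interest, so a
documented, reproducible quota rule is required; the plain equal-per-bin
rule is available as `mode = "equal_bins"`. Sampling is uniform without
replacement within bins, so the output is a strict subset of the input;
infeasible targets fail with the achievable range. On the canonical
synthetic study (100 patients, ~5,000 points, natural ΔMean ≈ 12 mmHg)
the resampled ΔMean lands within ±0.25 mmHg of 5.01.

Demographic cohort filters implement the age-band experiments (young
18–55, old 67+, the 56–66 band excluded from both) and the ASA-class-2
restriction.

# Numerical choices and degenerate inputs

* Intervals are half-open `[start, end)`; time is seconds from record
  start; sample indices are 0-based in time arithmetic.
* Event boundaries are strict: any valid second at or above threshold
  terminates a run.
* All-constant waveforms yield zero beats (not an error); fully masked
  MAP series yield zero events; burden on a zero-valid-duration series is
  an error.
* Ties at the decision threshold classify positive.
* Degenerate all-equal score sets cannot reach the specificity target;
  the report then carries the achieved value and a warning flag.
* The exponential-tilt bisection runs 200 iterations on `[-50, 50]`,
  ample for monotone bin-mean interpolation at any realistic bin count.

# Problem sizes in the test suite

The suite validates study-scale behavior on a 100-patient, two-hour-record
cohort (~5,000 labeled points) for the standardization experiment, a
16-patient cohort for labeling/leakage properties, two 50-patient twin
cohorts for the cross-dataset transfer experiment, 1,000 random MAP series
for event-detection equivalence, 10,000 random framing instances for the
labeling truth table, and a 200-point separable toy set for CNN
convergence. These sizes were chosen so the full suite demonstrates each
property at a scale where sampling error is negligible relative to the
tolerances tested.

# Known limitations

* The generator's morphology is a fixed template; detectors tuned on it
  are not validated against morphological variability, arrhythmia, or
  damped catheter traces.
* The abnormality rule thresholds are standard but not harmonized against
  any specific monitor's signal-quality index.
* WFDB and HDF5 readers are not provided; the interchange formats are CSV
  waveforms and JSON sidecars.
* No significance testing between predictors is implemented (only
  fold-aggregated confidence intervals), and no hyperparameter search.
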