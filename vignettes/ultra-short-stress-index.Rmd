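---
title: "Ultra-short-term estimation of the Baevsky Stress Index from PPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultra-short-term estimation of the Baevsky Stress Index from PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prvstress)
```

## The question

Short-term heart rate variability analysis conventionally asks for 5 minutes
of signal, and even "ultra-short-term" stress assessment typically uses a
full minute. That rules out genuinely real-time stress monitoring. The
question this package studies: if the *target* is the stress index computed
from one minute of photoplethysmography (PPG), how much accuracy is lost
when the *inputs* — time-domain pulse rate variability (PRV) features — are
computed from only 5, 10, 20, 30, 40, 50 or 60 seconds of signal?

The pipeline is: PPG waveform → NN intervals → 18 time-domain PRV features →
Baevsky Stress Index → sliding-window regression dataset → a four-regressor
× seven-window-length grid of 10-fold cross-validated R² scores.

## The stress index

For an NN-interval segment, build a histogram with fixed 50 ms bins anchored
at 0 ms. With Mo the modal-bin midpoint in seconds, AMo the percentage of
intervals in the modal bin, and MxDMn the range of the raw intervals in
seconds,

$$ SI = \frac{AMo}{2\,Mo\,MxDMn}. $$

Sympathetic activation makes beats faster and more uniform: the histogram
narrows and grows a taller mode, AMo rises, MxDMn shrinks, and SI increases.
A relaxed distribution gives SI roughly in the 80–150 range; acute stress
multiplies it several-fold. Reading AMo as a *percentage* (not a fraction)
is what places resting values in that conventional range, which is why the
implementation fixes that unit. Regression uses √SI as the label, the usual
damping of the index's heavy right tail.

Conventions the formula leaves open, fixed here: bins are `[k·50, (k+1)·50)`
ms; modal ties break toward the lower bin (determinism); Mo is the modal-bin
midpoint (configurable via `bin_width`; midpoint vs lower edge changes SI by
under 5% for resting distributions); Mx and Mn come from the raw intervals,
not bin edges. A segment with MxDMn = 0 has an undefined SI and raises an
error; windowed callers drop such windows and count them.

## Synthetic cohort

The study design this emulates — 17 subjects, 6-minute finger-PPG
recordings at 255 Hz in three states (rest, after two sets of push-ups,
after four sets) — used human data that cannot be redistributed, so the
package generates a synthetic stand-in with the same structure
(`generate_cohort()`; 51 recordings).

Beat-to-beat intervals follow a sinusoid-plus-noise model: mean RR plus
respiratory modulation (~0.25 Hz), low-frequency modulation (~0.1 Hz), and
Gaussian jitter, with phases randomised per recording so windows are not
phase-locked. This is deliberately simpler than an integral-pulse-frequency
model; it is the simplest structure that gives every time-domain feature a
nontrivial, state-dependent distribution. Default state parameters:

| state | mean RR (ms) | jitter SD (ms) | resp amp (ms) | LF amp (ms) |
|---|---|---|---|---|
| rest | 850 | 30 | 40 | 25 |
| exercise_2set | 650 | 14 | 18 | 11 |
| exercise_4set | 520 | 7 | 9 | 5 |

Rationale: the published protocol bounds the extreme state (a maximum
recorded heart rate of 158 bpm), so the most intense state sits at 520 ms
(115 bpm mean) with instantaneous rates peaking in the 150s; variability
shrinks monotonically with intensity, which is the physiological signature
the stress index keys on. With these defaults the median resting SI is
~85–90 (inside the conventional 80–150 resting band) and the post-exercise
states are several-fold higher — mild-to-severe stress territory. No
per-state distributional statistics were published, so these values are a
qualitative calibration, chosen once; per-subject perturbations (mean RR ±
N(0, 40 ms), amplitudes × U(0.85, 1.15)) add between-subject spread.

Waveforms are rendered by summing a fixed pulse template at each beat time —
a unit-height systolic Gaussian (σ = 60 ms) plus a 30% dicrotic bump at
+250 ms — plus sinusoidal baseline wander (0.1 Hz, below the pulse band),
white noise, and optional transient spike artifacts at Poisson times. The
bump delay keeps the filter-smeared bump inside the peak detector's
refractory distance (fs/3 samples ≈ 333 ms), so it is never mistaken for a
beat; only peak *times* matter downstream, so the template's exact shape is
otherwise a free choice. What the generator does **not** emulate: motion
artifacts with realistic morphology, sensor saturation, respiratory-rate
drift, ectopic beats with compensatory pauses, or any hemodynamic coupling.
Passing tests therefore certify the pipeline's arithmetic and its
qualitative behaviour on plausibly structured signals, not clinical
performance on real recordings.

## Preprocessing

`preprocess()` composes five deterministic stages:

1. **Trim** 30 s from each end (sensor settling; a 6-min recording keeps
   5 min).
2. **Band-pass** 0.5–3.0 Hz (36–180 bpm), a 4th-order Butterworth applied
   forward-backward so group delay cannot bias peak times. The signal is
   odd-reflection-padded before filtering: the 0.5 Hz edge has a
   multi-second impulse response and unpadded `filtfilt` start-up transients
   would otherwise distort the first and last beats.
3. **Peak detection**: local maxima with prominence ≥ 0.3 × signal SD and a
   minimum separation of fs/3 samples (the 3 Hz band edge implies no true
   beats closer than 1/3 s); the higher peak wins a distance conflict. The
   detection algorithm is parameter-light on purpose — the upstream filter
   already fixes the plausible beat band.
4. **Outlier flagging**: one non-iterative pass; an interval is flagged when
   |x − mean|/SD ≥ T with T = 2, using the population SD over the whole
   trimmed recording. Signed-vs-absolute, sample-vs-population SD and
   iteration are all unstated in the protocol this follows; absolute value,
   population SD and a single pass are fixed here and tested as such.
5. **Replacement**: each flagged interval becomes the median of its nearest
   surviving neighbours on either side (for two values, their mean);
   boundary runs copy the single nearest survivor. Interval count is
   preserved, and intervals are kept as real-valued milliseconds throughout.

Two consequences worth knowing. With Gaussian jitter, roughly 1–4% of
intervals in a perfectly clean recording still exceed |z| = 2 — the T = 2
rule trims distribution tails, not just artifacts — so a handful of replaced
flags on clean data is expected behaviour, not a defect. And beats whose
pulse is truncated by the trim boundary can shift by a few samples; interior
beats are recovered to within the two-sample quantisation bound (±7.8 ms at
255 Hz), which the tests assert.

## Features, windows, and selection

`compute_features()` returns the 18 standard time-domain features (mean,
median, SD, range, min/max of NN intervals; RMSSD and SDSD of successive
differences; NN50/pNN50 and NN20/pNN20; CVSD and CVNNI; mean/max/min/SD of
per-beat instantaneous heart rate). Conventions: sample SD (n − 1)
throughout; strict `>` for the 50/20 ms difference counts with the interval
count as pNN denominator; heart-rate statistics on per-beat 60000/NNᵢ.
Median NNI is the median of the intervals themselves — the name's standard
meaning — not a median of successive differences.

`slide_windows()` starts a window every second from t = 0 to
duration − 60 s, so the number of samples per recording is independent of
the feature window length L and every L shares identical √SI labels:
differences across L are attributable to the features alone. An interval
belongs to a window when its ending beat falls inside it. The label always
comes from [t, t+60); features come from [t, t+L).

Feature selection mirrors the study rule: a feature survives at window
length L if the R² between its short-window values and its source
recording's full 5-min value is at least 0.6 (reference as target, so
negative scores are possible and do occur for dispersion features at short
L). Selection runs once on the pooled samples before any CV split — as the
original workflow implies — which leaks label-free information across folds;
that optimism is accepted to stay faithful, and the grouped-CV audit below
bounds the larger leakage source anyway. Selected rows are then scaled to
unit L2 norm per sample ("normalizer" scaling; z-score standardisation is
available as an alternative for sensitivity checks).

## Models and evaluation

Four regressors, library defaults, no tuning: extremely randomised trees
(`ranger`, 100 trees, random split points, no resampling), gradient-boosted
trees (`xgboost`, 100 rounds, learning rate 0.1, depth 3 — the classic
boosting defaults), k-nearest neighbours (k = 5) and ordinary least squares.
Stochastic models take their seed from the `model_spec`; fold assignment is
seeded; the whole grid is reproducible bit-for-bit.

Each cell of the grid is the mean over 10 folds of the out-of-fold R² (test
fold's own mean as baseline). The per-length average over the four models is
the headline row; applied to the published per-model grid this averaging
rule reproduces the published means (0.7414 at 10 s, 0.9805 at 60 s) under
round-half-up to four decimals, which is how `grid_mean_row()` rounds.

Default folds are sample-level, matching the study protocol. Because
1-s-stride windows overlap by up to 59/60 of their span, sample-level folds
are strongly optimistic: near-duplicates of every test window sit in
training. `cross_validate(..., group_by = "recording")` holds out whole
recordings instead; on the synthetic cohort the grouped scores drop
substantially (the kNN model, which profits most from duplicates, falls the
furthest). The default reproduces the protocol; the option measures its
optimism.

## Problem sizes and runtime choices

The shipped analyses and tests use the full synthetic design — 51
recordings of 6 min, ~12,000 window samples per length, the complete
4 × 7 grid — for the headline run (a few minutes on one core), and smaller
cohorts (5 subjects, 3-min recordings, three window lengths) for
multi-seed tendency checks such as "tree ensembles ≥ OLS", where 5 seeds ×
a reduced grid answers the question at a fraction of the cost. Property
tests on the estimators use 1,000 random interval series against
brute-force oracles.

## Known limitations

* Published per-cell R² values were produced on 17 human recordings that
  are not redistributable; the synthetic cohort reproduces the *structure*
  of that experiment, so only rule-level quantities (selection counts,
  averaging) and qualitative properties (monotone accuracy in L, tree ≥
  linear, grouped < pooled) are checked against the publication, not the
  per-cell grid itself.
* The accuracy grid inherits sample-level-fold optimism by design; grouped
  CV is the honest generalisation estimate and is consistently lower.
* The z-score rule is single-pass and scale-global; slow heart-rate drift
  within a recording inflates the SD and can hide local outliers.
* Frequency-domain and nonlinear HRV indices are out of scope, as is any
  categorical stress staging.
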