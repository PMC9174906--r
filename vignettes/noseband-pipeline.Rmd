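---
title: "Offset-invariant chewing-behavior recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Offset-invariant chewing-behavior recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nosebandr)
```

## The problem

A noseband pressure sensor is a load cell strapped over a cow's nose bridge.
Jaw movement modulates the measured pressure quasi-periodically, so the
signal carries enough information to distinguish rumination (slow, highly
regular chewing, roughly 0.6–0.9 Hz), eating (faster and more irregular,
roughly 1.0–1.5 Hz), and everything else. The practical obstacle is the
*initial pressure*: when the device is strapped on, a constant baseline is
established that depends on the animal's head shape and how tightly the
halter was fitted. It is stable within a wearing but differs by hundreds of
grams between animals and between fittings. Any feature that depends on the
signal's location (its mean, minimum, quantiles, RMS) therefore confounds
behavior with fitting, and a classifier trained on raw values partly learns
the strap, not the cow.

This package implements a pipeline that removes the offset before
classification, and an evaluation harness to quantify what that buys.

## Pipeline

1. **Segmentation** (`segment_windows`): the labeled 50 Hz stream is cut
   into non-overlapping windows of fixed duration (10 s by default; 5, 15,
   20 and 30 s are the other sizes the sweep covers). A window is the unit
   of classification and carries exactly one label; windows containing a
   label change are discarded, as is a trailing partial window. No sample
   is used twice.

2. **Offset-eliminating preprocessing** (`first_order_difference`,
   `local_slope`, `highpass_butterworth`), compared against the untouched
   signal (`none`):

   * *First-order difference (FOD)*: `d[t] = x[t+1] − x[t]`. A constant
     cancels exactly; the output is one sample shorter. Each isolated
     mechanical spike turns into two large opposite excursions, so FOD is
     spike-sensitive.
   * *Local slope (LS)*: the ordinary-least-squares slope of each 11-sample
     sliding window (stride 1) against the unit-spaced abscissa
     `c = (1, …, 11)`,
     $$\hat s_t=\frac{N\sum_i c_i x_i^{*}-\sum_i c_i\sum_i x_i^{*}}
       {N\sum_i c_i^{2}-\left(\sum_i c_i\right)^{2}},\qquad N=11,$$
     reported in grams per sample step and associated with the window's
     center sample. A 30-sample segment yields exactly 20 slopes. Offsets
     cancel exactly, and averaging over 11 points suppresses isolated
     spikes far better than FOD — the package's tests assert
     `max |LS| < max |FOD|` on spike-contaminated simulations.
   * *High-pass Butterworth (HPF)*: sixth order, 0.3 Hz cutoff at 50 Hz,
     which is below the chewing band but above DC. Output length equals
     input length; DC gain is exactly zero, so a constant decays — through
     a transient, see below — rather than cancelling instantaneously.

3. **Feature extraction** (`fdf`, `tdsf`):

   * *FDF*: the one-sided, unnormalized FFT magnitude spectrum, excluding
     the DC bin. An n-sample window gives `floor(n/2)` magnitudes at
     `k·fs/n` Hz; 500 samples at 50 Hz give exactly 250 features at 0.1 Hz
     spacing covering 0.1–25 Hz. Excluding DC makes FDF *exactly* invariant
     to a constant offset, which is why even the raw-signal FDF pipeline
     tolerates offsets; preprocessing still helps by whitening the spectrum
     the classifier sees.
   * *TDSF*: 14 time-domain statistics in fixed order — mean, variance, SD,
     max, min, range, median, Q1, Q3, IQR, RMS, movement variation,
     skewness, kurtosis. Seven of these are location-dependent, which is
     precisely the mechanism by which offsets hurt the raw-TDSF pipeline.

4. **Classification and evaluation** (`behavior_classifier`,
   `cross_validate`, `run_comparison`): XGBoost with a fixed global
   hyperparameter set (100 trees, depth 6, learning rate 0.4, gamma 0.1,
   subsample 0.8, min_child_weight 1), k-nearest neighbors (k = 5), an RBF
   SVM, and a CART decision tree. Stratified 5-fold cross-validation; every
   window is predicted exactly once; per-fold confusion matrices are summed
   into a total confusion matrix from which accuracy, one-vs-rest
   precision, recall and F1 are computed (division-by-zero cases return 0
   with a note). `run_comparison` evaluates all preprocessing × scheme ×
   algorithm cells with *identical* fold assignments, so cell differences
   are paired, not resampling noise.

## The synthetic herd

No public recording of this kind exists, so the package ships a generative
stand-in (`simulation_config`, `simulate_series`, `simulate_herd`) and all
quantitative claims in the tests are claims about it. One simulated wearing
is:

* a constant `initial_offset` (drawn per wearing in `simulate_herd`,
  default range 30–400 g, bracketing the 28.6–232.3 g minima the three-cow
  setting exhibits);
* a bout schedule of labeled behaviors;
* per bout, a chew train: chew periods drawn around a per-bout base
  frequency (rumination 0.6–0.9 Hz with 3% relative period jitter, eating
  1.0–1.5 Hz with 15% — rumination is by definition the regular behavior),
  each chew a rectified half-sine pulse with per-chew amplitude drawn from
  150–350 g. Chewing is interrupted by the behaviors' documented
  micro-structure: rumination proceeds in bolus cycles (chewing 35–60 s,
  then a 3–6 s swallowing/regurgitation pause), eating alternates 5–20 s
  chewing bursts with 1–4 s prehension pauses;
* "other" behavior: low-amplitude broadband noise (SD 8 g) plus rare
  isolated bumps (head movement), clearly aperiodic;
* Gaussian baseline noise (SD 5 g) and sparse mechanical spikes
  (2 per minute, 100–300 g, 1–3 samples wide), clipped to the sensor's
  0–2000 g range.

All randomness derives from one seed; per-wearing seeds are
`seed + 10007·i`, so a herd is reproducible bit for bit. Amplitude
defaults were fixed once from the raw-trace ranges a three-cow setting
exhibits (offsets plus chew excursions reaching roughly 450–620 g) and are
plausible rather than fitted — no amplitude distribution for single
behaviors is published.

What the simulator does *not* emulate: sensor drift, battery and
temperature effects, behavior transitions inside a bout, cud-specific chew
counts, inter-animal differences in chew waveform shape, and annotation
noise. Passing tests therefore demonstrate that the pipeline's mechanics
(offset elimination, spectral separation, protocol bookkeeping) work as
specified — not that the specific accuracies transfer to field recordings.

## Numerical choices

* **Filter realization.** The order-6 highpass at 0.3/25 normalized
  frequency has all poles clustered near z = 1; evaluated as a single
  direct-form transfer function it leaves a ~1e−4 g floor on a constant
  input. The filter is therefore designed and applied as three cascaded
  biquads (analog Butterworth prototype → highpass transform at the
  pre-warped cutoff → bilinear transform → conjugate pole pairing), each
  section normalized to unit Nyquist gain; a constant then decays below
  1e−10 g. The filter is causal by default (matching streaming use on a
  wearable); `zero_phase = TRUE` gives a forward–backward pass.
* **Documented HPF transient: 45 s.** A 1000 g step — the largest offset
  difference the invariance tests exercise — falls below 1e−6 g after
  about 41 s; 45 s is the settled region used wherever "post-transient"
  appears.
* **Bit-exact offset invariance** holds for FOD and LS when `x + c` is
  exact in double arithmetic (integer grams, as a quantized sensor
  reports); for arbitrary doubles the float addition itself perturbs last
  bits, and agreement is asserted at 1e−9 instead.
* **FDF conventions.** 250 features from a 500-sample window force
  dropping either DC or Nyquist; DC is dropped because it carries the
  offset. Magnitude is the unscaled complex modulus. On FOD- and
  LS-shortened windows (499 and 490 samples per 10 s window) the spectrum
  is computed on the actual length (249 and 245 bins) rather than padded;
  feature length stays consistent within a pipeline, which is all the
  classifiers require.
* **TDSF conventions.** Variance/SD use the n−1 denominator; quartiles use
  linear interpolation between order statistics (R type 7); movement
  variation is the mean absolute successive difference; skewness is the
  biased moment estimate and kurtosis the Fisher excess form, both defined
  as 0 on zero-variance windows. Multi-axis correlation features from the
  accelerometer literature have no referent for a single pressure channel
  and are excluded.
* **HPF before segmentation, FOD/LS after.** The filter transient makes
  per-window filtering wrong, so the HPF pipeline filters whole series and
  then segments; FOD and LS are pure local transforms and run per window,
  keeping per-window feature length deterministic.
* **Fold assignment** is stratified by label (unstratified equal splits
  can produce degenerate folds at desk scale) and shared across cells for
  paired comparisons. Windows of one animal may appear in both training
  and test folds, mirroring a pooled-data protocol; this measures
  within-population generalization, not transfer to unseen animals.
* **Windows align to series start**; whether alignment to bout starts
  would change anything is untested and assumed immaterial.

## Problem sizes used by the test suite

The end-to-end suite simulates 3 animals × 5 daily wearings (one 120 s
bout per behavior per wearing, about 90 minutes of signal in total, 180
pure 10 s windows per class) — enough for the 5-fold protocol to have
≥ 100 windows per class while keeping a full run of the suite under a
minute. Per-wearing offsets are the package's reading of how such a
deployment behaves: re-strapping establishes a new baseline each time,
which is exactly what makes the offset a nuisance variable rather than a
proxy for animal identity.

## Known limitations

* The simulator is the package's own model of the signal; its realism
  ceiling bounds what the evaluation can show (see above).
* The timing column of `window_size_sweep` is wall-clock and
  hardware-dependent; it is reported for orientation only and never
  asserted against.
* KNN/SVM/DT hyperparameters are fixed documented defaults, not tuned;
  the comparison is between pipelines under equal treatment, not a
  benchmark of tuned classifiers.
* `read_pressure_csv` accepts numeric-seconds or ISO-8601 time columns
  only, and requires a uniform grid; gap-filling and resampling are out of
  scope.
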