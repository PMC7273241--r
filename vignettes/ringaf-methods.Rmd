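---
title: "Detecting atrial fibrillation from finger photoplethysmography: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting atrial fibrillation from finger photoplethysmography: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Atrial fibrillation (AF) produces an *irregularly irregular* pulse: the
intervals between consecutive heartbeats lose the quasi-periodic structure of
sinus rhythm (SR) and become essentially structureless. Because every heart
beat drives a blood-volume pulse at the periphery, a photoplethysmography
(PPG) sensor worn on a finger sees this irregularity directly in the timing
(and, through the pulse deficit, the amplitude) of successive pulses.
`ringaf` implements a complete screening pipeline around this observation:

1. **`ppg_synth`** — a synthetic PPG cohort generator, so every downstream
   stage is testable without access to clinical recordings;
2. **`preprocess`** — recording I/O, a 0.2–18 Hz zero-phase bandpass,
   resampling to 50 Hz, and overlapped window segmentation;
3. **`features`** — pulse-peak detection and classical rhythm statistics
   (RMSSD, Shannon entropy, waveform autocorrelation, coefficient of
   variation, pulse rate);
4. **`models`** — a linear-kernel SVM per feature set and a nine-layer 1-D
   convolutional network on raw windows, both emitting a calibrated
   "diagnostic confidence";
5. **`evaluation`** — repeated subject-level five-fold cross-validation,
   the standard diagnostic metrics with AF as the positive class, ROC AUC
   with a stratified-bootstrap CI, sample-length and decile stratification
   studies, a premature-beat-burden study under two randomization schemes, a
   confidence-threshold sweep, and external validation on an all-SR cohort.

## The synthetic cohort generator

No public dataset accompanies the problem, so the generator is a first-class,
tested component. It emulates precisely the statistical structure the
classifiers exploit, and nothing more:

* **SR beat trains.** Intervals are the base interval $60/\mathrm{HR}$
  modulated by a sinusoid at the respiratory rate (default 0.25 Hz, relative
  depth 0.03 — respiratory sinus arrhythmia) plus zero-mean Gaussian jitter
  scaled so the realized interval coefficient of variation (CV) matches the
  requested value. The default SR target CV is 0.05.
* **AF beat trains.** Intervals are i.i.d. log-normal with the requested
  mean and CV (default 0.25): strictly positive, right-skewed, and
  structureless — the "randomness of peak-to-peak intervals" that motivates
  interval-based AF detection. The log-normal choice is a modeling decision;
  nothing downstream depends on its exact shape, only on the realized CV.
* **Premature beats** (SR only). Each eligible sinus beat spawns, with
  probability equal to the burden, a premature beat at a fixed coupling
  fraction (default 0.6) of the preceding interval, followed by a full
  compensatory pause (the next sinus beat stays on the underlying grid).
  This is the simplest model that reproduces the clinically relevant
  feature: short coupled intervals followed by pauses that mimic AF
  irregularity inside a window.
* **A refractory floor of 0.25 s** is enforced everywhere by redrawing
  violating intervals; specifications whose interval law would violate the
  floor too often (probability above 0.25) are rejected as infeasible rather
  than silently distorted.
* **Waveform rendering.** Each beat contributes a stereotyped two-lobe
  template (a systolic Gaussian bump, $\sigma = 0.055$ s, plus a dicrotic
  bump of 0.45 relative amplitude delayed 0.25 s, $\sigma = 0.07$ s).
  With amplitude modulation on, pulse height scales linearly with the
  preceding interval, clamped to $[0.4, 1.2]$ of nominal — the pulse
  deficit of short AF diastolic intervals. This gives the CNN a morphology
  cue beyond timing, as real AF PPG has.
* **Noise.** Zero-mean white noise at a requested SNR (power ratio against
  the clean signal) plus a sinusoidal baseline wander with seed-derived
  phase. The reference conditions use 20 dB SNR and wander of amplitude 0.1
  at 0.2 Hz.

Everything is a pure function of its seed; per-recording seeds derive from
the cohort seed and subject index through an integer mixing function, so
cohorts are bit-reproducible.

**What the generator does *not* model** — and hence what passing tests do
not show about real data: optical and hemodynamic physics, motion artifacts
with autocorrelated structure, sensor saturation, other atrial
tachyarrhythmias, ectopy patterns beyond single coupled premature beats, and
drift in pulse morphology. The benchmark results below are statements about
the pipeline's correctness under its own study conditions, not clinical
performance estimates.

### Reference study conditions

`benchmark_cohort_config()` fixes the conditions used across the test suite
and the acceptance script: 20 AF subjects (interval CV 0.25) and 20 SR
subjects (CV 0.05, premature burden spread evenly over 0–0.1), one 15-min
recording per subject at 50 Hz and 20 dB SNR, heart rates spread over
realistic resting ranges (AF 58–95, SR 52–85 beats/min, overlapping, AF
slightly faster). `sr_cohort_config()` is the external-validation
counterpart: 20 healthy SR subjects with burden 0–0.05.

## Preprocessing

The pipeline order is fixed and documented: **filter → resample →
segment**. The bandpass is a recursive Butterworth design (order-4 transfer
function) applied forward and backward, so pulse peaks suffer no phase
shift. Resampling is band-limited polyphase interpolation with an identity
fast path at 50 Hz.

Segmentation emits 30-s windows every 10 s (20-s overlap). A window is kept
iff its end lies strictly before the recording's end, with a half-sample
tolerance so the rule is robust to floating rounding; a recording exactly
one window long yields that single window. Under this convention a 900-s
recording yields 87 windows, and a 20-subject cohort 1,740 — the only
boundary convention consistent with that printed total. Shorter samples
(25, 20, 15, 10, 5 s) are derived by truncating each 30-s window to its
leading seconds, which keeps per-length sample counts identical and metric
rows comparable across lengths.

## Features

The peak detector smooths with a 0.1-s moving average, thresholds at a
rolling 0.7 amplitude quantile (2-s windows on a 0.5-s grid, interpolated),
and resolves conflicts with a 0.3-s refractory rule in which the larger peak
wins. The refractory window also suppresses the dicrotic lobe, which trails
the systolic apex by about 0.25 s. Any detector that recovers ground-truth
beats to within ±40 ms with ≥ 99% sensitivity and precision at 20 dB would
be acceptable; the tests enforce exactly that. One caveat is inherent to
windowing, not to the detector: a pulse whose apex falls within ~0.3 s of a
window border is only partially rendered inside the window (sometimes only
its dicrotic lobe is), so recovery is asserted for apices at least 0.3 s
inside the window.

The interval statistics follow their textbook definitions: RMSSD is the
root-mean-square of successive interval differences; the CV uses the sample
(n−1) standard deviation; Shannon entropy uses 16 equal-width bins over the
window's own interval range, natural logarithms, normalized by
$\log 16$ to $[0,1]$, with all-equal intervals defined as 0. The
autocorrelation feature is the normalized sample autocorrelation of the
mean-removed *waveform* (not the intervals) at lags 1–150 samples
(0.02–3.0 s at 50 Hz). Windows with fewer than two detected intervals have
undefined interval features: they are excluded from the SVM arms (the count
is reported) but remain available to the CNN.

## Models

**SVM arms.** A linear-kernel SVM (via `e1071`, interior-point SMO) on each
of three feature sets: `(RMSSD, ShE)`, the 150-lag autocorrelation vector,
and their 152-dimensional concatenation ("ensemble"). Features are
standardized with training-set statistics only. Probabilities come from a
logistic link fitted to the training decision scores.

**CNN.** Nine trainable layers: seven same-padded 1-D convolutions (kernel
width 7) with batch normalization, ReLU, and ×2 average-pooling after each
of the first six, then global average pooling and two fully connected
layers (width 16, dropout 0.5) ending in two logits. Channel widths are
4, 4, 8, 8, 16, 16, 32. Global average pooling lets one architecture serve
every window length from 30 s down to 5 s. Training uses Adam
(learning rate $10^{-3}$, batch 64, 12 epochs, L2 $10^{-4}$ on weights)
on per-segment z-scored raw windows. Two design notes:

* *Time-scale augmentation.* During training each window is resampled by a
  factor drawn log-uniformly from $[0.7, 1.43]$ (circular wrap). This
  changes the apparent pulse rate while leaving relative interval
  irregularity untouched, and exists to deny the network the pulse-rate
  shortcut: subject-level splits mean test subjects' rates are never seen
  in training, and a rate-keyed classifier generalizes poorly. Rate
  invariance is exactly the property a rhythm classifier should have.
* *Capacity and schedule.* The widths and epoch count were chosen as the
  smallest configuration that reliably separates the reference benchmark on
  a single CPU; the architecture is not a claim about an optimal network,
  and any seven-convolution + two-fully-connected realization with
  equivalent accuracy would be interchangeable.

**Calibration.** After training, a softmax temperature is fitted as a MAP
estimate on a held-out, subject-disjoint calibration split (20% of
training subjects): mean NLL of the scaled softmax plus a standard-normal
prior on $\log T$ weighted by the calibration set's *effective* sample
size. Overlapping windows from one subject are strongly correlated, so the
effective size is the number of calibration subjects, not windows; without
this, temperature estimates fitted on a handful of subjects carry enough
sampling noise to *worsen* the calibration of an already-calibrated model,
and on a perfectly separated calibration set the bare likelihood even
degenerates ($T \to 0$, saturating every confidence). Genuine
miscalibration still dominates the prior. Since dividing logits by a positive scalar never changes the
argmax, so predicted labels — and hence accuracy, sensitivity, specificity —
are invariant; only the confidence changes. The predicted class is the one
with higher calibrated confidence; an exact tie ($p_{AF} = 0.5$) is called
AF, since screening favors sensitivity. Confidence-threshold filtering
keeps predictions whose confidence strictly exceeds the threshold and
reports the filtered fraction.

## Evaluation protocol

Subjects are shuffled by seed and dealt into five near-equal folds; each
fold serves once as the test set with a configurable number of training
repetitions per fold under derived seeds (10 repetitions → the canonical 50
validation processes; the desk-scale benchmark uses 2). The participant is
the unit of splitting, and the no-leakage invariant (no subject contributes
windows to both sides of any process) is asserted at run time in every
process. Sample-randomized folds are available for the premature-burden
study's contrast, where windows of one subject may straddle the split —
exactly the optimistic scenario that contrast is designed to expose.

Metrics are the standard confusion-matrix ratios with AF positive;
undefined cells (e.g. sensitivity of an all-SR cohort) are reported as
absent, never as 0 or 1. AUC uses the rank (Mann–Whitney) identity, ties
counting one half, with a stratified bootstrap CI (2,000 resamples, seeded).
Decile stratifications compute boundaries within each true class
separately: sensitivity deciles over AF windows, specificity deciles over
SR windows. Burden bins are fixed at $\{0\}$, $(0,0.05]$, $(0.05,0.1]$,
$(0.1,0.2]$, $>0.2$. External validation re-runs inference ten times over
the healthy cohort and counts every pass (deterministic models repeat
identically, and are still counted), so 1,740 windows yield 17,400 test
cases. The 2-D visualization of the CNN's penultimate activations uses an
exact t-SNE (O(n²), suitable for a few thousand windows) implemented in the
package.

## Numerical choices and degenerate inputs

* Seeds: every stochastic step takes an explicit seed; child seeds derive
  from parent seeds and integer indices via exact integer mixing below
  $2^{31}$.
* The segmentation boundary rule uses a half-sample epsilon; the
  duration-equals-window case is special-cased to one window.
* Temperature search is one-dimensional on $\log T \in [\log 0.05,
  \log 20]$; fewer than 50 calibration samples, a single-class split, or an
  optimization failure fall back to $T = 1$ with a warning.
* Perfectly separated logistic links (possible on separable training sets)
  are clamped to $[10^{-6}, 1 - 10^{-6}]$ before log-likelihoods.
* Zero-variance windows yield a zero autocorrelation vector with a warning;
  flat windows yield empty peak series; both are excluded from feature-based
  arms and counted.
* Problem sizes: the reference benchmark (40 subjects × 87 windows = 3,480
  windows) is evaluated with 2 training repetitions per fold (10 processes)
  and the sample-length contrast at 30 s vs 5 s with 1 repetition per fold;
  these sizes keep a full run on one CPU in the tens of minutes while
  leaving the protocol identical in structure to the canonical
  5 × 10 = 50-process design.

## Known limitations

* The generator's realism bounds what the benchmark can certify (see
  above); in particular additive white noise is a mild stand-in for motion
  artifact.
* The premature-beat model uses a single fixed coupling fraction and full
  compensatory pauses; bigeminy, couplets, and interpolated ectopy are out
  of scope.
* The SVM probability link is a plain logistic fit, not Platt's regularized
  variant, which matters only near perfect separation where probabilities
  saturate anyway.
* The exact t-SNE is quadratic in the number of windows; embed subsamples
  beyond a few thousand.
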