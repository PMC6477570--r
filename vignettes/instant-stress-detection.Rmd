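---
title: "Instant stress detection from smartphone PPG and nose-tip thermography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instant stress detection from smartphone PPG and nose-tip thermography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pulseTherm implements an *instant* (single 20-second window) perceived-stress
detection pipeline built from two contact/contactless channels: a
blood-volume-pulse (BVP) signal extracted from smartphone camera frames via
spatial entropy, and a nose-tip thermal-variability signal from a thermal
camera. This vignette is the package's account of the method: what each stage
computes, why the numerical defaults are what they are, and where the
approach is fragile.

## The measurement problem

Perceived stress is conventionally assessed over minutes of physiology
(heart-rate variability needs long windows for its spectral indices) or by
questionnaire. The target here is different: decide *from one 20 s window*
whether the person is stressed, using sensors a phone either has or can
carry. Twenty seconds yields only ~20-28 heartbeats and ~20 thermal samples,
so every stage must squeeze positional precision out of very short records,
and classifiers must cope with few, noisy features.

## Channel 1: entropy-based PPG

A fingertip pressed on the camera lens modulates transmitted light with each
pulse. The classical signal is the spatial *mean* of the R channel. This
package's primary signal is instead the spatial Shannon entropy of the
8-bit brightness histogram (256 bins over 0..255, with the convention
0·log 0 = 0):

\[ H_t = -\sum_{j} p_{t,j} \log_2 p_{t,j} \]

Pulsatile blood volume perturbs the *spread* of the brightness distribution
even when the mean barely moves; the negated entropy \(-H_t\) therefore
rises at each beat. `spatialEntropy()` / `estimateRawBvp()` implement this;
`method = "mean_intensity"` keeps the classical baseline for comparison.

The per-frame series (native ~30 fps) is then:

1. **upsampled** to a uniform 256 Hz grid by cubic-spline interpolation
   (`resampleUniform()`), so peak positions can be resolved well below the
   33 ms frame period;
2. **amplitude-equalized** by subtracting a centered 1 s moving average
   (`equalizeAmplitude()`); 1 s spans at least one beat at any resting heart
   rate, so the average tracks baseline wander, not the pulse;
3. **peak-picked** by a strict local-maximum rule in a centered 0.5 s window
   (`detectPPIntervals()`), ties broken toward the earlier sample.
   Successive peak-time differences are the PP intervals; a validity filter
   keeps 500-1250 ms (48-120 bpm).

Two numerical details matter on 20 s records. First, near the record edges
the moving-average window is necessarily truncated; we measured that this
biases the first and last peak positions by ~25 ms even for a noise-free
synthetic pulse, while interior peaks are recovered to ~1 ms. `extractPPG()`
therefore discards peaks within half the moving-average window of the ends
(`edgeGuardS`). Second, the entropy estimate itself is a histogram statistic:
on a 32×32 crop (1024 pixels spread over 256 bins) its quantization noise
jitters recovered peaks by several ms, which is why the synthetic renderer
defaults to 64×64 frames.

## Channel 2: nose-tip thermal variability

Sympathetic vasoconstriction cools the nose tip within seconds of a
stressor. The raw ROI-mean temperature, however, is dominated by breathing
(warm exhaled air) in the 0.1-0.85 Hz band. `extractThermal()` computes the
low-level thermal signal as:

1. **uniform regridding** (linear interpolation at the median native frame
   interval; thermal cameras have unsteady frame rates);
2. **breathing removal** by a 7th-order zero-phase Butterworth low-pass at
   0.08 Hz (just below the breathing band's 0.1 Hz low edge). r-signal's
   `filtfilt` applies no edge padding, which at a 0.08 Hz cutoff on a 20 s
   record lets the edge transient swamp the signal, so the package
   implements the mainstream-DSP convention (odd reflection padding of
   3×order samples with steady-state initial conditions) on top of
   r-signal's `butter` design;
3. **1 Hz resampling and min-max scaling** to [0,1] per window
   (`variabilitySequence()`); a constant window scales to all-0.5 by
   convention, with a warning. The filtered °C series is retained alongside,
   because the temperature-difference feature is a physical temperature.

## Signal quality (pSQI)

`psqi()` scores a signal by the fraction of its spectral power inside an
expected band. The cardiac configuration (`cardiacPsqi()`) is 0.8-2.0 Hz
after a 0.7-4.0 Hz zero-phase band-pass prefilter; the respiratory
configuration (`respiratoryPsqi()`) is 0.1-0.85 Hz with no prefilter, used
before/after breathing removal as an effectiveness check.

The PSD estimator is Welch's method (Hann window, 10 s segments, 50%
overlap) with one deliberate deviation: segments are **linearly detrended**
rather than merely mean-removed, and the respiratory configuration uses one
full-record segment. With 10 s mean-detrended segments the lowest resolvable
bin sits exactly at the 0.1 Hz respiratory band edge, and residual slow
trends leak enough power into the band that a perfectly breathing-free
signal can still score > 0.2. With linear detrending and a full-record
segment, synthetic breathing-contaminated series score > 0.9 raw and < 0.05
after filtering, mirroring the intended use. The cardiac configuration is
insensitive to this choice.

## Features

From the valid PP intervals (`prvFeatures()`): SDPP, RMSSD, pPP50
(proportion of successive differences > 50 ms — by default relative to the
number of intervals; the conventional successive-difference denominator is a
config switch), and LF (0.04-0.15 Hz), HF (0.15-0.40 Hz) and LF/HF from the
periodogram of the 4 Hz linearly-interpolated tachogram. Time-domain
features require ≥ 4 valid intervals, spectral ones ≥ 8; anything
uncomputable is `NA`, never silently zero. On 20 s the LF estimate is
acknowledged to be at the resolution limit — it is kept for completeness,
not trusted in isolation.

From the thermal channel (`thermalFeatures()`): TD (last minus first
filtered °C, negative = cooling), and the SDs of the scaled variability
sequence and of its successive differences (SDTV, SDSTV).

## Labeling self-reports

Each session yields a 0-10 visual-analogue stress score. Because people use
such scales with very different offsets and ranges, scores are min-max
normalized per participant before pooling (`normalizeScores()`). Binary
labels come from four strategies (`assignLabels()`): L1/L2 cluster the
pooled normalized scores with k-means, k = 3, and call either the lowest
cluster (L1) or the two lowest (L2) "NoStress"; L3 uses k = 2; L4 thresholds
the *raw* scale at 10/3 (the 10 cm line cut into three equal parts). The
k-means is the package's own exact 1-D dynamic program (`kmeans1d()`):
optimal 1-D partitions are contiguous in sorted order, so the global optimum
is found deterministically — no random restarts, no initialization
sensitivity, and the L1 ⊃ L2 stress-set nesting is a testable invariant.

## Classifiers and evaluation

Low-level encodings (`encodeLowLevel()`) give the networks fixed-width
inputs: valid PP intervals linearly interpolated over beat index to 40
points, the thermal sequence truncated/edge-padded to 20. NN1 (80 hidden
units) and NN2 (260) are single-hidden-layer sigmoid networks with a single
sigmoid output trained by per-sample SGD under binary cross-entropy
(learning rate 0.5, 100 epochs, reshuffled each epoch, uniform(-0.1, 0.1)
init). All randomness is drawn in R from one seed; the update loop runs in
C++ and is deterministic, so training is bit-reproducible. The kNN
comparator (k = 1, Euclidean on train-set z-scored features, ties to the
earliest training index) uses the 9 engineered features.

Evaluation is leave-one-subject-out (`losoCv()`): one fold per participant,
features z-scored by each fold's training set, accuracy and macro-F1 per
fold, confusion accumulated across folds. LOSO is the honest protocol here —
any within-person leakage wildly inflates accuracy for physiological
signals.

## Synthetic cohorts

No recordings ship with the package; `generateCohort()` replaces them. The
default cohort emulates a lab stress protocol (17 participants × 6 sessions:
two rests, two easy and two hard stressor tasks) with planted effects *and*
the between-person physiology that makes LOSO hard:

- a latent stress level per session (rests ≈ 0.10, easy ≈ 0.55, hard ≈ 0.90,
  plus participant and session noise);
- an AR(1) PP-interval generator calibrated to target SDPP/RMSSD
  (`generateRR()`), with baseline RMSSD log-normal across participants
  (median 45 ms, log-SD 0.35 — resting HRV spreads ~35-45% between people)
  and *multiplicative* stress suppression (default 35% at full stress;
  HRV indices scale with a person's own baseline);
- frame stacks whose histogram spread breathes with the planted pulse
  (`renderPpgFrames()`), so the entropy pathway — and not the mean-intensity
  baseline — recovers the beats;
- thermal series with breathing contamination, sensor noise, timestamp
  jitter, and a stress-dependent cooling trend (default −0.03 °C/s at full
  stress) on top of a participant drift bias (SD 0.01 °C/s, the same order
  as modest stress effects);
- VAS scores with participant-specific offset and range compression, the
  distortion per-participant normalization is designed to undo.

These defaults deliberately put the engineered features in a weak-effect,
high-heterogeneity regime: a high-baseline participant's stressed RMSSD
overlaps a low-baseline participant's rest, so a nearest-neighbour on
9 summary features no longer wins for free, and sequence-level models have
something real to add — qualitatively matching real instant-window data,
where feature-to-stress correlations are weak. With `sessionStress` set to a
binary contrast and effects raised ("RMSSD halved, slope −0.05 vs 0"), the
plant is strong and multimodal NN2 LOSO accuracy exceeds 0.85.

## Problem sizes and runtime

A 20 s window is ~600 camera frames (64×64) and ~160 thermal samples; a
full default cohort is 102 windows. On one CPU: cohort generation with
frames ~50 s, signal-only ~2 s; full-cohort PPG extraction ~30 s; one
17-fold NN2 LOSO evaluation ~6 s (the SGD loop is C++); kNN LOSO < 1 s.

## Limitations

- The renderer is a statistical stand-in (one fixed spatial pattern whose
  scale breathes with blood volume), not an optical model; it exercises the
  histogram-entropy pathway but cannot probe motion artifacts, ambient
  light, or skin-tone effects.
- 20 s spectral features (LF especially) are at the resolution limit;
  treat them as weak learners, not measurements.
- The first/last half-second of each window contributes no beats by design
  (edge guard); pipelines needing every beat must record margins.
- Acceptance-style claims about classifier orderings are statistical
  properties of cohort seeds, not theorems; individual seeds can invert
  them.
- Synthetic VAS noise is Gaussian and unimodal; real self-reports are
  lumpier (anchoring, digit preference), which would stress the k-means
  labeling differently.
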