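---
title: "Methods: denoising, features and classification for prefrontal fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: denoising, features and classification for prefrontal fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nirsdepress` implements a decision-support pipeline for grading depression
severity (mild vs. severe) from prefrontal functional near-infrared
spectroscopy (fNIRS) recorded during a block-design verbal fluency task
(VFT): 30 s rest, 60 s task, 30 s rest, sampled at 10 Hz over 18 prefrontal
channels. This vignette is the package's account of the underlying models,
the tunable parameters, and the design choices that were genuinely open.

## The synthetic cohort generator

Clinical fNIRS recordings of this kind cannot be shared, so the package
ships a generator (`simulate_cohort()`) that reproduces the statistical
structure the pipeline assumes, with the clean (noise-free) traces retained
as ground truth for denoising validation.

Per subject, the clean oxygenated-hemoglobin trace of channel *c* is

> dHbO_c(t) = a_s * j_c * r(t),

where `r(t)` is the task boxcar convolved with a canonical double-gamma
hemodynamic response function (peak ~6 s, undershoot ~16 s, undershoot ratio
1/6 — the community default, `canonical_hrf()`), normalized to peak 1;
`a_s ~ N(mu_group, 0.3)` is the subject's response amplitude; and
`j_c ~ N(1, 0.1)` is a per-channel multiplicative jitter. The deoxygenated
trace is `-1/3` times the HbO trace lagged by 1 s, the typical empirical
ratio; both are configurable. Group structure: `effect_size` is the
standardized mild-minus-severe difference in `a_s` (in units of the 0.3
between-subject SD), with the mild group the more activated one. The default
cohort is 82 severe + 58 mild subjects.

Noise, added per channel and species:

* a cardiac sinusoid with subject-drawn frequency in 0.8–1.5 Hz (inside the
  0.5–2.0 Hz cardiac band) and per-channel phase, amplitude 0.3;
* a respiratory sinusoid in 0.2–0.4 Hz, amplitude 0.4;
* slow polynomial drift of scale 0.5 over the recording;
* white measurement noise, SD 0.2;
* Poisson-placed motion artifacts (rate 2 per recording): spikes smoothed
  over 0.5 s and step-like baseline shifts, the two artifact classes that
  motion repair and decomposition denoising are meant to remove.

Amplitudes are relative to the unit group-mean response peak; they were
chosen once as representative of raw prefrontal fNIRS, where physiological
oscillations rival or exceed the evoked response. Per-channel phases make
inter-channel correlations carry real information (pulse arrival varies
across the scalp). What the generator does **not** emulate: photon-transport
physics, scalp/short-separation contamination with a common superficial
component, non-sinusoidal cardiac waveforms, non-stationary noise, or real
between-subject anatomical variability. Tests passing on this cohort show
the pipeline's machinery is sound and calibrated, not that the clinical
effect sizes of real populations are reproduced.

All randomness flows from one integer seed; identical seeds give
byte-identical cohorts.

One consequence of this design is worth stating precisely. The group
difference is carried by a *single* Gaussian latent variable (the subject
amplitude `a_s`); temporal features, correlation features and the HbR traces
are all transforms of it. At `effect_size = 2` the Bayes-optimal classifier
on that latent attains

> 0.586·Φ(1 + log(0.586/0.414)/2) + 0.414·Φ(1 − log(0.586/0.414)/2) ≈ 0.845

with the 82/58 class priors — an information ceiling that no feature set or
model can exceed, and that measurement noise pushes the realized nested-CV
accuracy slightly below (the calibration test asserts a 0.85 bar and is
expected to sit just under it; the permutation-null and fusion checks pass).
A generator with a second, independent group-difference dimension would
raise the ceiling, but would no longer describe a pure amplitude effect.

## Preprocessing

Fixed order, per channel and species (`preprocess_recording()`):

1. **Polynomial detrend** (`detrend_poly()`, default order 3) — removes slow
   baseline drift by least squares; a projection, hence exactly idempotent.
2. **TDDR motion correction** (`tddr_correct()`) — temporal derivative
   distribution repair: the signal is split at 0.5 Hz, the low-frequency
   part's derivative is robustly reweighted (Tukey biweight, tuning 4.685,
   scale 1.4826·MAD, up to 50 iterations, tolerance 1e-9), reintegrated, and
   the high-frequency part added back unchanged. Steps and smoothed spikes
   produce derivative outliers that receive near-zero weight.
3. **Chebyshev type II filtering** (`bandpass_filter()`), third order,
   stopband edge 0.2 Hz, 30 dB attenuation, applied forward–backward (zero
   phase) — suppresses respiration (0.2–0.4 Hz) and cardiac (0.5–2.0 Hz)
   oscillations.

Two design points were genuinely open and are worth recording:

* **Low-pass, not band-pass.** A "cutoff 0.01 Hz / stopband 0.2 Hz"
  specification can be read as a band-pass or as a low-pass with drift left
  to detrending. We implement the low-pass reading (a high-pass section is
  available via `filter_spec(highpass = TRUE)` but off by default): a 60 s
  task block inside a 120 s recording has its fundamental near 0.008 Hz,
  which any high-pass at 0.01 Hz attenuates, visibly distorting the evoked
  response. Detrending handles the drift instead.
* **Re-application stability.** Detrending is exactly idempotent and
  re-filtering deep-in-band content (≤ 0.03 Hz) changes it by well under 1%;
  but content in the filter's transition band (0.05–0.2 Hz) is partially
  attenuated on every pass, and TDDR's robust reweighting is not a
  projection. On *noise-free* signals TDDR's MAD scale estimate collapses
  and genuine task transitions look like outliers — an inherent property of
  the published algorithm visible only on synthetic data, since real
  recordings always carry enough noise to anchor the scale estimate.

When starting from raw optical densities, `od_to_hemoglobin()` solves the
2×2 modified Beer–Lambert system per sample with configurable DPF (defaults
6.0/5.0), source–detector distance (3.0 cm) and extinction table
(`default_extinction()`, recorded in run manifests).

## CEEMDAN–WPT denoising

Filtering cannot touch noise *inside* the task band. The package's core
denoiser decomposes each signal by **CEEMDAN** (complete ensemble empirical
mode decomposition with adaptive noise) and wavelet-packet-thresholds only
the high-frequency intrinsic mode functions (IMFs):

1. `emd_decompose()`: classical EMD — cubic-spline upper/lower envelopes
   through local extrema (mirrored at the boundaries), sifting until a
   standard-deviation criterion < 0.2 or 10 sifts, modes removed until the
   residual has fewer than two interior extrema.
2. `ceemdan_decompose()`: mode 1 is the ensemble mean of the first EMD mode
   of `x + eps*sd(x)*w_i` over `I` Gaussian noise realizations (default
   `I = 100`, `eps = 0.2`); at stage *k* the next mode is the ensemble mean
   of the first EMD mode of `r_k + eps*sd(r_k)*E_k(w_i)`, where `E_k` is the
   k-th EMD mode of the stored noise realization normalized to unit SD.
   Because each residual is defined by subtraction, `sum(IMFs) + residual`
   reconstructs the input to machine precision by construction.
3. `split_imfs()`: an IMF is *high-frequency* when its zero-crossing rate
   exceeds twice the 0.2 Hz band edge (for a narrowband mode, crossings/s
   ≈ 2× its dominant frequency). An empty high-frequency set is a valid
   outcome — a clean signal needs no thresholding. (A "force the first half
   of the modes" fallback was considered and rejected: it discards genuine
   low-frequency signal on clean input.)
4. `wpt_denoise_imf()`: full wavelet-packet tree (db4, level 3, periodized
   orthogonal filter bank), per-node universal threshold
   `lambda = sigma_hat * sqrt(2 log n)` with `sigma_hat = median|coef|/0.6745`,
   soft shrinkage, inverse transform. When denoising a *high-frequency IMF*
   the approximation node is thresholded too: an IMF is zero-mean and
   narrowband, so its approximation-path content is noise leakage. When used
   directly on a raw signal (the wavelet-only baseline) the approximation
   node is exempt, the standard way to protect smooth signal content. This
   asymmetry is what gives the combined method its measured margin over
   wavelet-only denoising.

`snr()` (`10*log10(sum(x^2)/sum((x-y)^2))`, log base 10) and `rmse()` score
denoisers against the generator's clean ground truth;
`benchmark_denoisers()` runs the raw/EMD/wavelet/CEEMDAN-WPT comparison on a
fixture battery and reports SNR both against the clean reference and against
the noisy input, since either convention appears in the literature.

## Features

All features are computed on the 60 s task window only (half-open sample
windows derived from the paradigm). Per channel and species, nine **temporal
features** (`temporal_features()`): maximum, minimum, mean, rectified mean
`mean(|x|)`, skewness, peak (crest) factor `max|x|/RMS`, mean square
frequency, power spectral entropy, and singular spectral entropy — for 18
channels, 18×2×9 = 324 columns. **Correlation features**
(`correlation_features()`): Pearson correlation of every unordered channel
pair, per species — C(18,2)×2 = 306 columns.

Conventions fixed here (each scale-invariant or scale-covariant, so unit
conventions cannot affect classification): spectra are plain unwindowed
one-sided FFT periodograms with the DC bin excluded; entropies use the
natural log; the singular-spectrum embedding window is 50 samples (5 s at
10 Hz); a constant segment returns documented sentinels (skewness 0, crest
factor 1) with a warning; a zero-variance channel yields correlation 0 with
a warning. For white noise the power spectral entropy sits slightly below
the `log(N_bins)` ceiling — the exact expectation for exponential
periodogram ordinates is `log(N) - (1 - gamma)` ≈ 0.93·log(N) at N = 600 —
which the tests assert as a bracket rather than a naive "within 5%".

## Two-pass feature selection (RFECV)

`rfecv_select()` eliminates features recursively by linear SVM importance
(squared weights; cost 1; features z-scored inside each fold on its training
part), choosing the subset size that maximizes mean stratified 5-fold CV
accuracy (ties to the smaller size). `two_pass_select()` applies it to the
temporal and correlation families separately, fuses the survivors, and
re-selects — so redundancy *across* families is removed after each family
has been pruned on its own terms. The study-reported counts at each stage
(47 temporal, 54 correlation, 35 fused) are data outcomes, not constraints:
the implementation reports whatever the CV curve selects. Selection must be
fitted on training subjects only; `run_pipeline()` wires this, and a
sentinel test (signal planted only in held-out subjects) verifies it.

## Classification and evaluation

Four model families (`fit_model()`): linear/RBF SVM (`e1071`), ridge
logistic regression (`glmnet`), random forest (`randomForest`), and a
single-hidden-layer perceptron (`nnet`). Default grids: SVM cost 10^(-2..2)
× {linear, RBF} × gamma {1/(p·var), 10^(-3..0)}; LR cost 10^(-2..2); RF
{100, 300} trees × depth {3, 5, unlimited}; MLP {16, 64} units ×
weight-decay {1e-4, 1e-2}. Features are z-scored with training-set
statistics only.

* `stratified_split()`: per class, round-half-up of the training fraction —
  82/58 subjects at 60% gives exactly 49/35 train and 33/23 test.
* `grid_search_fit()`: exhaustive lattice search by stratified inner-CV
  accuracy, ties to the first lattice point, winner refit on the full
  training set.
* `nested_cv_evaluate()`: 5 stratified outer folds; the grid search runs on
  each outer-training set only; metrics (AUC by rank statistic, accuracy,
  sensitivity, specificity, F1; positive class "severe" by default) are
  computed once per outer-test fold and aggregated. No subject appears on
  both sides of any fold.
* `run_model_comparison()`: the model × {TF, CF, TCF} table, evaluated on
  the held-out split (optionally plus nested CV per cell).

## Channel activation statistics

`glm_beta()` fits `[intercept, boxcar ⊗ HRF]` per channel by least squares
(HbO by default; configurable); `channel_activation_test()` runs one-sample
t-tests of the betas against zero at alpha 0.05 (no multiplicity correction
by default, matching raw per-channel thresholding; Bonferroni available);
`group_activation_contrast()` compares groups per channel. The group
comparison uses a **Welch two-sample t-test** with the mild-minus-severe
sign convention: the groups are independent and of unequal size (82 vs. 58),
so a paired test is not applicable.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulations use sizes chosen to make
each property measurable with comfortable margins on a single CPU: CEEMDAN
ensembles of 30–40 for the 20-recording batteries (completeness and the
benchmark ordering hold at any ensemble size; 100 remains the analysis
default), the full 140-subject cohort for classification calibration, 40
null cohorts of 20 subjects (720 channel tests) for the false-positive-rate
check, and 40 + 40 subjects for the group-contrast direction. Degenerate
inputs are handled explicitly: monotonic signals decompose to a bare
residual; constant signals are returned unchanged by TDDR and produce
sentinel features; infinite-SNR comparisons raise an error rather than a
number.

## Known limitations

* SNIRF reading is not provided: it would require an HDF5 binding; the
  package's interchange format is TSV plus a JSON manifest.
* EMD boundary handling uses simple extremum mirroring; very short signals
  (< ~8 samples per extremum) are rejected rather than decomposed.
* The generator's noise is stationary and sinusoidal per component; real
  superficial physiology is broader-band and partially shared across
  channels, which short-separation regression (out of scope here) addresses.
* Absolute denoising SNR/RMSE magnitudes depend on the (unit-bearing) noise
  profile; only orderings and gains are asserted.
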