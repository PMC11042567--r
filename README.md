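# nirsdepress

Decision-support pipeline for grading **depression severity (mild vs.
severe) from prefrontal fNIRS** recorded during a block-design verbal
fluency task (30 s rest / 60 s task / 30 s rest at 10 Hz, 18 prefrontal
channels). The package is aimed at biosignal/neuroimaging researchers who
need the full chain — simulation, preprocessing, decomposition denoising,
feature engineering, leakage-safe feature selection and nested-CV model
evaluation — as composable, tested R functions.

Because clinical recordings of this kind cannot be shared, the package
includes a first-class synthetic cohort generator with task-locked
hemodynamics (double-gamma HRF), physiological noise (cardiac 0.5–2 Hz,
respiration 0.2–0.4 Hz, drift, white noise) and spike/step motion artifacts,
with the noise-free ground truth retained for denoising validation.

## What it computes

* **Preprocessing**: modified Beer–Lambert conversion (`od_to_hemoglobin`),
  polynomial detrending, TDDR motion correction (robust Tukey-biweight
  reweighting of the temporal derivative), zero-phase 3rd-order
  Chebyshev-II filtering (stopband 0.2 Hz).
* **CEEMDAN–WPT denoising**: complete ensemble empirical mode decomposition
  with adaptive noise (`ceemdan_decompose`; `sum(IMFs) + residual`
  reconstructs the input to machine precision), wavelet-packet soft
  thresholding (db4, level 3, per-node universal threshold
  `sigma_hat * sqrt(2 log n)`) of the high-frequency IMFs only
  (`ceemdan_wpt_denoise`), and an SNR/RMSE benchmark harness
  (`snr = 10 log10(sum x^2 / sum (x-y)^2)`).
* **Features** (task window only): per channel and species the nine temporal
  features — max, min, mean, rectified mean, skewness, crest factor
  `max|x|/RMS`, mean square frequency, power spectral entropy
  `H_f = -sum p_k log p_k` over the normalized periodogram, and singular
  spectral entropy over the Hankel trajectory spectrum — 18×2×9 = **324 TF**
  columns; plus Pearson correlations of all channel pairs per species,
  C(18,2)×2 = **306 CF** columns.
* **Two-pass RFECV**: recursive feature elimination (linear-SVM importances)
  with CV-optimal subset size, run on TF and CF separately, fused, and
  re-selected (`two_pass_select`).
* **Classification**: stratified 60/40 split (82/58 subjects → 49/35 train,
  33/23 test), grid search in an inner CV, nested cross-validation, four
  model families (SVM, ridge logistic, random forest, MLP), metrics
  (AUC, accuracy, sensitivity, specificity, F1) with the severe class as
  positive (`run_model_comparison`).
* **Activation statistics**: per-channel GLM betas against the
  boxcar-convolved HRF, one-sample activation t-tests, Welch two-sample
  group contrast with the mild-minus-severe sign convention.

## Worked example

```r
library(nirsdepress)

# a small synthetic cohort: 10 severe + 8 mild, 18 channels, seeded
spec   <- cohort_spec(n_severe = 10, n_mild = 8, effect_size = 2, seed = 42)
cohort <- simulate_cohort(spec)

# score denoisers against the clean ground truth on six fixtures
bench <- benchmark_denoisers(cohort[1:6], methods = c("none", "wavelet", "ceemdan_wpt"),
                             ceemdan = ceemdan_config(ensemble_size = 40, seed = 7))
print(attr(bench, "summary"), row.names = FALSE, digits = 3)
#>       method median_snr_vs_clean median_rmse
#>         none               -7.16       0.850
#>      wavelet               -6.82       0.788
#>  ceemdan_wpt               -6.46       0.712

# feature battery
labels <- cohort_labels(cohort)
proc   <- lapply(cohort, function(s) preprocess_recording(s$recording))
tf     <- build_feature_table(proc, "tf", labels)   # 18 x 2 x 9 = 324 columns
cf     <- build_feature_table(proc, "cf", labels)   # C(18,2) x 2 = 306 columns
dim(tf); dim(cf)
#> [1]  18 324
#> [1]  18 306
```

The benchmark says raw channels are noise-dominated (−7.2 dB against the
clean reference: physiological oscillations, drift and motion artifacts
rival the evoked response) and that wavelet thresholding recovers some of
it while CEEMDAN–WPT recovers the most, with the matching RMSE ordering —
motion steps are the job of the earlier TDDR stage, which is why the
pipeline applies preprocessing before decomposition denoising. The feature
tables have exactly the combinatorial column counts the 18-channel battery
implies.

A thin CLI over the same functions ships in `inst/cli/nirsdepress.R`
(subcommands `simulate`, `preprocess`, `denoise`, `features`, `select`,
`compare`, `activation`, `run-all`, `config`; exit codes 0/2/3), and
`run_pipeline()` orchestrates the full chain in R with a manifest for
reproducibility.

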