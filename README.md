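# radsig

Ultrasound radiomics signatures for disease-free survival modelling.

Papillary thyroid carcinoma has excellent survival, so risk stratification
targets **disease-free survival (DFS)** — months from surgery to
recurrence/persistence, censored at last follow-up. `radsig` asks whether
texture descriptors of the tumor's pretreatment ultrasound appearance add
prognostic value beyond clinicopathologic factors, and implements the full
analysis as a tested, reusable pipeline:

1. **Texture features.** From each ROI-masked grayscale tumor image, a
   fixed inventory of **730 features**: 14 first-order statistics, 22
   gray-level co-occurrence (GLCM/Haralick) features × 4 directions and 11
   gray-level run-length (GLRLM) features × 4 directions, computed on the
   original ROI and on the four subbands (LL/LH/HL/HH) of a single-level
   orthonormal Haar wavelet transform — 146 features × 5 channels.
2. **Radiomics signature (Rad-score).** LASSO-penalized Cox regression
   over the standardized features, tuned by 10-fold cross-validation
   (folds stratified on event status, penalty chosen by the minimum
   partial-likelihood-deviance criterion), repeated many times with
   coefficient averaging:

   `Rad-score_i = Σ_k  β̄_k · z_ik`

   where `z_ik` is feature *k* of patient *i* standardized by the training
   cohort, and `β̄_k` the averaged cross-validated LASSO-Cox coefficient.
   The signature keeps the `K` features of largest `|β̄_k|`, with `K` the
   rounded mean active-set size across repetitions.
3. **Incremental value.** Cox proportional-hazards models (Efron ties)
   with and without the Rad-score; Harrell's C-index for both; bootstrap
   resampling of subjects (fixed linear predictors) for the percentile 95%
   CI of the C-index difference.
4. **Synthetic cohort.** A generator emulating the study's structure
   (n = 768, ~11.1% events, median follow-up ≈ 117 months, published
   covariate prevalences) whose images carry a *planted* texture-hazard
   signal via speckle granularity — so recovery of the signal, and honest
   null behavior without it, are testable without any patient data.

## Worked example

```r
library(radsig)

cfg <- run_config(
  output_dir = "ptc_run",
  synthetic  = cohort_config(n_patients = 120),
  n_repeats  = 3,      # 100 for the full protocol
  n_boot     = 200,    # 1000 for the full protocol
  seed       = 11
)
res <- run_pipeline(cfg)
print(res$signature)
print(res$comparison)
```

```
Radiomics signature: 15 features (mean selected per repetition: 14.7 over 3 repetitions)
  original__glcm__contrast__d90            +0.6126
  LL__glcm__cluster_prominence__d90        -0.3813
  HH__glcm__correlation__d0                -0.3766
  HH__glcm__homogeneity__d90               +0.2598
  LH__glrlm__rp__d0                        +0.1752
  ...
C-index 0.815 (base) vs 0.967 (augmented); difference 0.152 (95% CI 0.034, 0.305) *
```

The signature found the planted texture signal (co-occurrence contrast and
correlation features dominate), and the radiomics-augmented model
discriminates DFS better than the clinicopathologic model alone — the
bootstrap CI of the C-index difference excludes 0 (the trailing `*`). At
this demonstration scale (120 patients, ~13 events) the estimates are
noisy; `ptc_run/` contains the feature table, signature JSON, per-patient
Rad-scores, univariate and multivariate model tables (CSV and Markdown),
the C-index comparison and a run manifest that makes the run exactly
reproducible.

Individual stages are exported for use on real data: `load_image()`,
`read_mask()` (PNG or polygon text), `apply_mask()`, `extract_all()` /
`extract_cohort()`, `standardize()`, `repeated_cv_select()`,
`rad_score()`, `fit_cox()`, `concordance_index()`, `compare_models()`.
A thin command-line front end with verbs `simulate`, `extract`,
`build-signature`, `evaluate` and `run-all` ships at
`inst/cli/radsig.R`.

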