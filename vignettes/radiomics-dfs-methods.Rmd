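---
title: "Ultrasound radiomics signatures for disease-free survival: methods"
author: "radsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasound radiomics signatures for disease-free survival: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Papillary thyroid carcinoma (PTC) has excellent long-term survival, so risk
stratification focuses on *disease-free survival* (DFS): the months from
initial surgery to recurrence or persistent disease, censored at last
follow-up. Clinicopathologic predictors (nodal metastasis, extrathyroidal
extension, tumor size, radioiodine dose, ...) are only fully known after
surgery. Pretreatment ultrasound images, by contrast, are available before
any treatment; radiomics asks whether quantitative texture descriptors of
the tumor's sonographic appearance carry independent prognostic signal.

`radsig` implements that analysis end to end: texture feature extraction
from ROI-masked grayscale tumor images, construction of a penalized-Cox
radiomics signature (the *Rad-score*), and quantification of the
signature's incremental value over a clinicopathologic Cox model through
bootstrap-compared Harrell C-indices. Because no patient images are
distributed with the package, a synthetic cohort generator reproduces the
*statistical* structure of such a study and plants a known texture-hazard
signal, so that every stage can be validated against ground truth.

## Feature extraction

Each tumor is represented by a grayscale image (RGB input is collapsed
with the BT.601 luminance weights 0.299/0.587/0.114) and a binary ROI
mask (PNG or filled polygon). The fixed inventory is 730 features:

* **5 channels** — the original ROI plus the four subbands (LL, LH, HL,
  HH) of a single-level orthonormal Haar wavelet transform. Subband masks
  keep a cell only when all four parent pixels are inside the ROI, falling
  back to "any parent" below 16 cells so tiny ROIs remain analyzable.
* **14 first-order statistics** per channel — moments (population
  convention, non-excess kurtosis), order statistics, energy, RMS, mean
  absolute deviation, and histogram entropy/uniformity on the quantized
  levels.
* **22 gray-level co-occurrence (GLCM) features × 4 directions** per
  channel — the classical Haralick set (contrast, correlation, cluster
  statistics, homogeneity variants, sum/difference statistics, information
  measures of correlation), at unit pixel distance, symmetric counting.
* **11 gray-level run-length (GLRLM) features × 4 directions** per
  channel — the Galloway/Chu set (short/long-run emphasis,
  non-uniformities, run percentage, low/high gray-level variants).

That makes 14 + 88 + 44 = 146 per channel and 730 in total, frozen in a
versioned manifest (`feature_manifest()`, shipped as JSON) whose order is
the canonical column order of every feature table the package writes.

Choices a user may care about:

* **Normalization.** Every ROI (and every wavelet subband, independently)
  is min-max rescaled to [0, 255] before quantization, so that texture
  features are comparable across patients and scanners. A consequence
  worth knowing: after min-max rescaling, the first-order minimum, maximum
  and range are constants and carry no information; they are retained for
  inventory stability and automatically flagged as zero-variance during
  modelling.
* **Quantization.** `Ng = 32` gray levels by default (configurable).
  Level = `min(Ng, floor((v - min)/(max - min) * Ng) + 1)`, a rule
  invariant under any increasing affine rescaling of intensities.
* **Wavelet basis.** Single-level orthonormal Haar. The transform is
  exactly invertible and energy-preserving (both properties are tested),
  and its block structure makes arithmetic exactly reproducible across
  platforms. Odd dimensions are extended by half-sample symmetry before
  analysis; subbands have ceiling-half sizes.
* **Directions** (0°, 45°, 90°, 135°) are kept separate rather than
  averaged; averaging is a common variant but halves nothing here — the
  730-feature inventory is defined with directions distinct.
* Texture features are invariant under translations of the ROI by even
  pixel offsets; odd offsets change the 2x2 wavelet block alignment, so
  the wavelet-channel features (only) can shift slightly. This is inherent
  to any decimated wavelet transform.

Degenerate inputs: a constant ROI quantizes to level 1 everywhere, all
entropies and variances are 0, GLCM correlation is defined as 0 (its
zero-variance limit), and the information measures of correlation use the
`0 log 0 = 0` convention — the feature vector stays finite and complete.

## The radiomics signature

With 730 correlated features and few events, the signature is built by
L1-penalized (LASSO) Cox regression:

1. Features are z-scored (population SD); zero-variance columns are
   excluded from selection.
2. One repetition: 10-fold cross-validation, folds stratified on event
   status so every fold keeps events at an ~11% event rate, over a
   log-spaced path of 100 penalties from `lambda_max` down to
   `0.01 lambda_max`. The penalty minimizing the cross-validated
   partial-likelihood deviance ("minimum criterion", no 1-SE rule) is
   kept, and the coefficients are re-fit on the full data at that penalty.
   Ties inside the penalized fits use the Breslow approximation.
3. The repetition is repeated `n_repeats` times (100 by default) with
   fresh fold assignments; coefficient vectors are averaged elementwise.
   The signature keeps the `K` features with largest absolute averaged
   coefficient, where `K` is the rounded mean number of selected features
   across repetitions (ties broken by manifest order); an explicit `K`
   can be supplied instead.
4. The Rad-score of a patient is the weighted sum of the selected
   features, standardized with the training-cohort center/scale and
   weighted by the averaged coefficients. It is linear in standardized
   feature space by construction.

Averaging full-data refits at each repetition's `lambda_min` (rather than
averaging fold-level fits) is the standard practice with the penalized
Cox software this procedure mirrors; repetition damps the fold-assignment
randomness that makes single cross-validated LASSO selections unstable.

A numerical note: the coordinate-descent convergence threshold defaults
to `1e-5` (rather than the underlying solver's `1e-7`). At this problem's
scale the selected penalty and active set are unchanged and coefficients
agree to ~2e-3, while fits are several-fold faster; the threshold is an
argument if tighter convergence is wanted.

## Survival evaluation

Cox proportional-hazards models are fitted by maximum partial likelihood
with Efron tie handling (survival times in months are heavily tied).
Hazard ratios are reported with Wald 95% CIs. Discrimination uses
Harrell's C-index with the strict comparability rule: pair (i, j) counts
when `t_i < t_j` and subject i had the event; tied risk scores receive
half credit.

The incremental value of the Rad-score is assessed by fitting the
clinicopathologic model and the augmented model (same covariates plus
Rad-score) on the same subjects, holding both linear predictors fixed,
resampling subjects with replacement (1,000 times by default), and taking
the percentile 95% CI of the C-index difference; the improvement is
called significant when that CI excludes 0. Refitting both models per
resample is available behind a flag (`refit = TRUE`) but is not the
default: the fixed-predictor comparison answers "do these two fitted
scores rank this cohort differently", which is the published comparison.
Percentile rather than BCa intervals keep the procedure simple and
transparent.

## The synthetic cohort

The generator emulates the structure of the study population rather than
ultrasound physics:

* n = 768 patients; binary covariate prevalences (age ≥ 55: 0.229, male:
  0.156, nodal metastasis: 0.595, distant metastasis: 0.012), log-normal
  tumor size (median 16 mm, clipped to 2–65 mm) and a discrete radioiodine
  dose distribution with median 30 mCi. Gross extrathyroidal extension
  uses prevalence 0.3: the published count for that characteristic is
  internally inconsistent, so it is a configuration key rather than a
  copied value.
* Survival follows a Weibull proportional-hazards model (shape 1.2, a
  mildly increasing hazard — any baseline suffices for recovery tests)
  with uniform administrative censoring over 80–154 months. The baseline
  scale is *calibrated by root finding* so the expected event fraction is
  0.111 given the cohort's linear predictors; the censoring window was
  chosen so the median observed follow-up lands near 117 months, matching
  the reported cohort.
* Effect sizes default to the published multivariate model: the texture
  effect is log(3.087) per SD of a standard-normal latent risk, and the
  clinical log hazard ratios are those of the multivariate
  radiomics-model column. In the feature-level simulator the planted
  per-feature effect is log(3.087)/√10, splitting the same signature-level
  hazard ratio evenly across 10 planted features.
* Images are 64 × 64 px with an elliptical ROI (~600–1,250 px) on a smooth
  background. The texture signal enters through *granularity*: a
  speckle-like field mixes coarse (spatially correlated) and fine
  (independent) grain with a mixing weight monotone in the latent risk, at
  constant amplitude, plus sparse Gaussian clutter blobs whose density and
  contrast rise with risk. Amplitude-based signals would be inverted or
  erased by per-ROI min-max normalization; arrangement-based signals
  survive it. Empirically, ROI GLCM entropy and contrast rise with latent
  risk, GLCM correlation falls.
* Clinical covariates and latent texture risk are drawn independently —
  the true joint distribution is unknowable from published summaries, and
  independence makes "incremental value" in the synthetic world
  unambiguous.

What passing tests on this cohort do *not* show: performance on real
ultrasound (no beam physics, attenuation, operator variability, or
scanner differences), robustness to segmentation error, or transportable
effect sizes. The generator supports inference about the *pipeline* —
recovery of planted signal, honest null behavior — not about PTC.

## Problem sizes used by the test suite

The test suite runs the full study-scale configuration where the claim
depends on it (n = 768 cohorts for signature recovery and the end-to-end
discrimination checks, with 20 cross-validation repetitions for feature
recovery, 3 for the 20-cohort end-to-end loop, and 500 bootstrap
resamples) and small fixtures everywhere else. The acceptance script runs
one full n = 768 pipeline at 20 repetitions and 1,000 bootstrap
resamples. With the published settings (100 repetitions) the signature is
slightly more stable but materially unchanged; `n_repeats` is a single
argument when the full protocol is wanted.

## Selection optimism on null data

The signature is selected on the full cohort and the bootstrap comparison
evaluates it on that same cohort with fixed linear predictors — the
standard design when no validation cohort exists. The cost is *selection
optimism*: on cohorts
with no texture-hazard association at all, the minimum-deviance penalty
rule occasionally locks onto a set of mutually correlated noise features —
repetition averaging does not help, because repetitions only re-randomize
fold assignment, not the data the spurious association lives in — and the
in-sample C-index comparison can then reach nominal significance. In the
package's own 10-cohort null experiment this happens in roughly 1–2
cohorts in 10. The 1-SE penalty rule would damp it but is deliberately not
used (the implemented protocol specifies the minimum criterion); the
honest remedies are an external validation cohort — which studies of this
design typically lack — or the refit-per-resample comparison mode
(`compare_models(refit = TRUE)`), which is provided but not the default. Users applying the pipeline to real data should treat an
in-sample C-index gain as an upper bound.

## Known limitations

* 2D single-image analysis only: no 3D, shape, or filter-bank (e.g.
  Laplacian-of-Gaussian) features; tumor size enters as a clinical
  covariate, not an image feature.
* The exact published feature inventory is reconstructed from its stated
  family structure and total count (5 × (14 + 22×4 + 11×4) = 730); the
  manifest documents the reconstruction and is versioned so it can be
  revised.
* No proportional-hazards diagnostics, competing risks, or time-dependent
  covariates.
* The published signature's exact 40 features and coefficients depend on
  the original patient images and are not reproducible from summaries;
  the package reproduces the *method*, with the signature size emerging
  from the data (typically 30–45 on default synthetic cohorts).
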