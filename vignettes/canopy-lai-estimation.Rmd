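---
title: "Estimating canopy LAI from multispectral plot imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating canopy LAI from multispectral plot imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Leaf area index (LAI, one-sided leaf area per unit ground area, m²/m²) is
the central state variable of crop canopy monitoring. Spectral vegetation
indices (VIs) computed from multispectral reflectance track LAI well at
low and intermediate canopy density but saturate as the canopy closes:
once gaps become rare, band ratios such as NDVI barely move while LAI
keeps rising. Spatial texture carries complementary information — a
closing canopy becomes spatially *smoother*, so gray-level co-occurrence
(GLCM) statistics keep responding after the spectral signal flattens.

`canopyLAI` implements a complete estimation pipeline on five-band
(B 450, G 560, R 650, RE 730, NIR 840 nm) plot imagery:

1. **Spectral features** — ROI band means and 11 VIs (`computeVIs()`).
2. **Texture features (TFs)** — 8 GLCM metrics × 5 bands = 40 features
   per plot, from a sliding-window engine (`textureFeaturesForSample()`).
3. **Texture indices (TIs)** — two-component (NDTI, DTI, RTI) and
   three-component (NDTTI, DTTI, RTTI) combinations of selected TFs,
   enumerated combinatorially and ranked by correlation with LAI
   (`enumerateCandidates()`, `selectTopIndices()`).
4. **Screening** — Pearson correlation with significance filtering
   (p < 0.05), re-applied inside training folds during cross-validation
   (`screenFeatures()`).
5. **Stacked regression** — a PLSR base learner paired with one of SVM /
   RF / GBDT; out-of-fold predictions of the two bases form two
   meta-features on which a Lasso meta-model is fitted (`fitStack()`).
6. **Evaluation** — a rank-systematic 2/3–1/3 split (`sortedSplit()`),
   R²/RMSE/MAE (`laiMetrics()`), transfer to a distribution-shifted
   independent scenario (`evaluateScenarios()`), and coarse LAI maps
   (`predictMap()`).

## Texture engine

Each band is quantized to 32 gray levels by per-ROI linear min–max
mapping. A 4 × 4 window slides at stride 1; within each window the
co-occurrence matrix at the single symmetric displacement (dx = 1,
dy = 1) is formed and the eight metrics (mean, var, hom, con, dis, et,
sem, cor) computed; metrics are averaged over window positions. Design
choices worth stating explicitly:

* **32 levels** balances statistical stability inside 4 × 4 windows
  (24 symmetric pixel pairs) against discretization loss; it is a
  configuration parameter, not a constant.
* **Per-ROI min–max quantization** makes every texture feature invariant
  to affine per-band radiometric error — the property that lets texture
  survive calibration drift that corrupts VIs.
* **Energy (`sem`)** is the angular second moment Σp², not its square
  root.
* **Correlation of a zero-variance window is defined as 0**, keeping
  window averages finite on homogeneous canopy.
* Metric-level averaging (not pooled counts) across windows matches the
  texture-map-then-ROI-mean practice of plot-level reporting.
* The engine is compiled (Rcpp) and stores window pair counts sparsely;
  a brute-force R oracle in the test suite verifies it to 1e-10 on
  random images.

## Texture indices

With T1, T2 (and T3) the ordered component features:
NDTI = (T1−T2)/(T1+T2), DTI = T1−T2, RTI = T1/T2,
NDTTI = (T1−T2−T3)/(T1+T2+T3), DTTI = T1−T2−T3, RTTI = T1/(T2·T3).
RTTI is read as a ratio-family index T1/(T2·T3). Candidates are
enumerated exhaustively over the selected TF pool rather than sampled
randomly — the exhaustive set is the reproducible superset of any random
draw. The three-component families are symmetric in T2 ↔ T3, so only the
canonical ordering is kept (for 10 TFs: 3·90 two-component plus 3·360
three-component candidates). Ranking uses Pearson |r| with a p < 0.05
filter; ties break lexicographically so the ranking is deterministic.

## Stacked model

PLSR handles the strong collinearity of the VI/TF/TI block by latent
variables (`mixOmics::pls`, components searched in 1..15 capped by the
data); the nonlinear base (SVM: `e1071`, RF: `ranger`, GBDT: `xgboost`)
captures the saturating, interacting response. Both bases are tuned by
grid search minimizing inner-CV RMSE. Out-of-fold meta-features are
built with k = 5 folds (a compromise between meta-feature bias and
training-set size at n = 120); inside every meta fold the bases are
re-tuned so no sample's meta-feature ever comes from a model that saw
it. The meta-model is a Lasso (`glmnet`, penalty by cross-validation):
with only two, highly correlated meta-features, L1 shrinkage
automatically downweights the redundant base. PLSR and SVM inputs are
z-scored with training statistics; tree learners consume raw features.
Full-range default grids are in `defaultGrids()`; `reduced = TRUE`
yields compact grids for cross-validated runs at simulation scale.

`nestedCvEvaluate()` re-runs the *entire* procedure — screening, tuning,
meta-features, meta-model — inside every outer training fold and returns
out-of-fold predictions with fold bookkeeping, so leakage can be audited
directly (corrupting a fold's labels must not change that fold's
predictions; the test suite does exactly this).

## The synthetic trial

Field reflectance campaigns are rarely redistributable, so the package
carries a generator whose defaults emulate the trial structure the
analysis assumes: 3 planting densities × 4 nitrogen rates × 3 replicates
= 36 plots, imaged on 5 dates → 180 plot-date samples; a shifted
independent scenario has 4 dates, darker soil and a higher noise floor.

* **LAI trajectories.** A gamma-shaped seasonal curve peaks at date 4
  (early grain filling) and declines; density and nitrogen scale the
  amplitude, with the nitrogen response saturating above the N2 rate so
  the D3N2 treatment attains the maximum. Plot-level lognormal noise
  (log-sd 0.08, plus a replicate effect of log-sd 0.05) is applied and
  values are clipped to [0.77, 5.28] m²/m².
* **Scenes.** A two-endmember (leaf/soil) mixture: leaf discs of radius
  3 px are stamped at random until the visible-soil fraction reaches the
  Beer–Lambert gap fraction exp(−k·LAI) with k = 0.6; leaf and soil draw
  fixed five-band spectra, scaled by a per-date illumination gain drawn
  uniformly in [0.9, 1.1], perturbed by per-pixel Gaussian noise
  (sd 0.01) and clipped to [0, 1].
* **Acquisition variability.** Two per-sample channels emulate
  flight-to-flight variation: a per-band calibration gain jitter
  (log-sd 0.03), to which VIs are sensitive but min–max-quantized
  texture is invariant; and a noise-floor jitter (log-sd 0.25), which
  inflates contrast-type TFs across all bands jointly and which
  cross-band texture *ratios* largely cancel. These channels create, by
  construction, the structure the method exploits: VIs saturate and
  drift, TFs are radiometrically robust, TIs are additionally robust to
  shared texture inflation.
* **Default image size** is 128 × 128 px per plot ROI — large enough for
  stable GLCM statistics (15,625 window positions), small enough for
  desk-scale runs.

What the generator does **not** emulate: radiative transfer (no PROSAIL
leaf biochemistry), reproductive organs (tassels), row structure,
shadows, view-angle effects, or orthomosaic artifacts. Passing tests on
synthetic data therefore demonstrate the pipeline's internal
correctness, leakage safety and qualitative behavior (feature fusion
helps; texture resists radiometric drift), not field-accuracy claims.
The synthetic scenes are also cleaner than real imagery, so absolute R²
values on them run higher than one should expect in the field.

## Numerical and procedural choices

* **Split rule.** "Sorted, 1/3 validation" is implemented as systematic
  rank sampling: ranks 2, 5, 8, … (capped at n−1) go to validation, so
  both sets span the LAI domain and the extremes stay in the modeling
  set. For n = 180 this gives exactly 120/60.
* **Zero denominators** in any ratio index (VI or TI) yield `NA`,
  flagged, never infinities; correlation ranking drops such samples
  pairwise.
* **Screening** uses alpha = 0.05 with no multiple-testing correction —
  a deliberate mirror of common practice in this literature and a
  documented statistical caveat; it is applied to the full modeling set
  for the deployed feature lists and re-applied per training fold for
  cross-validated performance.
* **Degenerate inputs.** Constant bands quantize to level 0; constant
  windows give con = dis = et = var = 0, hom = sem = 1, cor = 0;
  constant responses abort model fitting with an explicit error; R² of a
  constant observed vector is `NA` with a warning.
* **Determinism.** One root seed drives the generator, fold assignments
  and the stochastic learners through independent derived streams;
  regeneration and refitting under the same seed are bitwise identical.
* **Problem sizes.** The test suite exercises the full 36-plot × 5-date,
  128 px configuration for the design-count and signal-recovery checks
  (five generator seeds with the reduced grids), and a 24-plot-date,
  48 px configuration for unit-level checks; the null-control uses 20
  permutation replicates of a 72-sample table. These sizes were chosen
  to keep a complete run at desk scale.

## Known limitations

* The generator's two-endmember radiometry cannot produce VI–LAI
  relations with realistic chlorophyll dynamics; CIRE and GNDVI behave
  like structural indices here.
* GLCM parameters (window 4, offset (1,1), 32 levels) are fixed
  defaults; sensitivity to flight altitude or window size is out of
  scope.
* The Lasso meta-model fuses exactly two base learners; wider stacks
  would need a different meta-feature builder.
* `predictMap()` reuses plot-level feature definitions at tile scale;
  tiles smaller than ~16 px give unstable texture features.
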