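---
title: "Radiomic prediction of re-excision after breast conservation surgery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic prediction of re-excision after breast conservation surgery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After breast conservation surgery (BCS), pathology sometimes finds tumor at
or within 1 mm of the inked specimen margin, and the patient returns for a
re-excision. HER2-overexpressing cancers are re-excised particularly often.
Pre-operative dynamic contrast-enhanced MRI (one pre-contrast and three
post-contrast T1-weighted acquisitions, with the tumor contoured once on the
first post-contrast series and the contour mapped to the other three) is
routinely available, so the question this package operationalizes is: do
quantitative features of the contoured tumor volume predict which lesions
will need re-excision?

The pipeline has four stages, each exposed as ordinary functions:

1. **Feature extraction** — per lesion: 3 shape features computed once from
   the shared mask (`roi_solidity()`, `roi_extent()`,
   `roi_eccentricity()`), and per timepoint 6 first-order histogram
   features, 4 gray-level co-occurrence matrix (GLCM) features and 11
   gray-level size zone matrix (GLSZM) features on intensities quantized to
   16 levels — 87 features in total.
2. **Univariate screening** — Spearman rank correlation of each feature
   with the binary endpoint, plus a two-sample t-test between outcome
   groups (`univariate_screen()`).
3. **Multivariate model** — an RBF-kernel SVM (`C = 1000`,
   `gamma = 0.005`) evaluated by leave-one-out cross-validation; inside
   each fold, features are ranked by the BW-ratio (between- to within-group
   sums of squares) on the training rows only, and models are trained on
   the top `k` features for `k = 1..30` (`loocv_sweep()`).
4. **Synthetic cohort** — a phantom generator (`cohort_spec()`,
   `generate_cohort()`) that emulates the statistical structure of the two
   outcome classes so every stage can be tested end to end without patient
   data.

## Feature definitions and conventions

Where the field has competing conventions, the package pins one and keeps
it switchable behind an explicit argument:

* **Solidity** counts voxels: foreground voxels divided by the number of
  grid voxel centers inside or on the convex hull of the foreground voxel
  centers. Counting hull-interior voxels (rather than comparing mesh
  volumes) matches the pixel-counting framing of extent and avoids
  mesh-volume convention disputes. Masks whose foreground is coplanar or
  collinear have no 3D hull and fail loudly; the extraction pipeline skips
  and logs such lesions rather than imputing.
* **Extent** is foreground voxels over the tight axis-aligned bounding-box
  volume.
* **Eccentricity** is not defined by a single standard in 3D. The package
  uses the meridional eccentricity of the best-fit ellipsoid:
  `sqrt(1 - lambda_min/lambda_max)` of the spacing-scaled covariance of
  foreground voxel centers. Whether historical implementations used 2D
  slice ellipses or a 3D fit is not recoverable; the 3D definition is
  isolated behind one function so an alternative is a one-line change.
* **Kurtosis** is Pearson (non-excess; normal = 3). Skewness is
  `m3 / m2^1.5` with population moments. Zero-variance regions return `NA`
  with a warning, never a silent 0.
* **Quantization** is equal-width over the in-mask range of each scan
  separately (`level = min(L, floor((v - min)/(max - min) * L) + 1)`,
  L = 16). Per-scan quantization makes texture features invariant to global
  intensity scaling of a sequence, which is the relevant invariance for
  uncalibrated T1-weighted images. A constant region maps to level 1.
* **GLCM**: the 13 unique 3D directions at distance 1 voxel, pooled into a
  single symmetric matrix before normalization (fewer arbitrary numbers
  than per-direction averaging; the alternative is reachable through the
  `aggregate` argument). Homogeneity is inverse difference
  (`1/(1 + |i-j|)`); the inverse-difference-moment variant is available.
  Entropy uses log base 2 with `0 log 0 = 0`.
* **GLSZM**: zones are maximal 26-connected equal-level components (the 3D
  analog of the original 8-connected 2D definition; 6-connectivity
  available). The 11 features are the standard size-zone set; the
  intensity-crossed emphases (LIZE, HIZE, LILZE, HILZE, ...) follow the
  `1/i^2`, `i^2`, `1/j^2`, `j^2` weight template.
* **Shape features are computed once per lesion** from the single mask, and
  reported under the `pre` tag, consistent with one contour mapped across
  all four timepoints.

## The classifier stage

The RBF kernel at `gamma = 0.005` is scale-sensitive, so features are
z-scored — using training-fold means and standard deviations only. The
no-leakage contract (fold-internal ranking *and* fold-internal
standardization) is asserted by recomputation in the tests. Ranking ties
are broken by feature name for reproducibility; a feature with zero
within-group scatter and distinct class means is a perfect separator and is
ranked first with an infinite ratio (logged). The reported `best_k` is the
smallest `k` maximizing LOOCV accuracy — the selection rule is a package
decision since no aggregation rule is standard. The consensus feature list
is ordered by mean rank across folds. Class weighting is not applied.
Sensitivity is the fraction of re-excision (label 1) lesions correctly
classified, specificity the fraction of no-re-excision (label 0) lesions;
both are reported with exact Clopper–Pearson 95% intervals.

## What the phantom generator emulates

Each lesion is one 26-connected mask shared across four timepoint volumes,
written as NIfTI with voxel spacing in the header plus a CSV manifest.

**Geometry.** The body is a `p = 3` superellipsoid (semi-axes
`base_radii`), carved by `K = 16` inward Gaussian dents on the radius field
(widths uniform in 0.15–0.35 rad, amplitudes `irregularity` times uniform
0.8–1.6). Two modeling choices deserve explanation:

* A plain ellipsoid fills its bounding box to only `pi/6 ~ 0.52`; carving
  it down to the solidity of an irregular lesion (~0.80) pushes extent far
  below anything seen in compact breast masses. The `p = 3` body starts at
  extent ~0.72, so both classes land in a realistic band (0.40–0.80).
* Dents are inward-only: they lower solidity monotonically in
  `irregularity` without inflating the bounding box, giving one parameter
  clean control of convexity. If a deep dent fragments the mask, the
  largest component is kept.

Calibration targets were the exemplar shape values of resected vs
re-excised lesions (solidity about 0.94 vs 0.80): `irregularity = 0.20`
gives class-0 mean solidity ~0.944 (extent ~0.55) and `0.52` gives class-1
mean ~0.805 (extent ~0.41), measured over 25 masks per class on a 36³ grid.

**Intensities.** Each timepoint gets an independent spatially correlated
skew-normal field: two i.i.d. standard-normal fields are smoothed with a
Gaussian kernel of width `texture_corr_length` (1.2 voxels class 0, 1.8
class 1 — the correlation is what creates non-singleton GLSZM zones),
standardized, and combined by the delta construction
`f = delta |g0| + sqrt(1 - delta^2) g1`. Order matters: smoothing *after*
skewing damps the third standardized moment by
`sum(w^3)/sum(w^2)^{3/2}` (about 0.1 at these widths) and erases the class
difference, which is why the construction skews the already-smoothed
fields — marginals are then exactly skew-normal with shape `skew_shape`
(−4 for the no-re-excision class, +4 for re-excision, following the
reported direction that re-excised lesions have less left-skewed
histograms). In-mask intensity is `enhancement_curve[t] * (100 + 20 f)`
(arbitrary units; curves 1/2.2/2.0/1.8 and 1/2.3/2.1/1.9 emulate wash-in
followed by mild washout); background is low-level non-negative noise.

**Seeds.** One master seed; lesion `i` uses substreams
`seed * 1e5 + 2i` (mask) and `+ 1` (intensities), so enlarging a cohort
never reshuffles existing lesions and every output is a pure function of
the specification.

**What it does not emulate** — and hence what passing tests do not show
about real data: bias fields, motion or fat-suppression artifacts,
multifocal disease, inter-reader contour variability, scanner and field
strength heterogeneity, and any realistic overlap between the classes. The
default presets separate the classes strongly (the calibration anchors
themselves are far apart), so the pipeline's discrimination on the phantom
is an upper bound, not an estimate of clinical performance; the
permutation-null check (`~0.5` accuracy under shuffled labels) guards
against optimism from the pipeline itself.

## Numerical choices

* The 3D convex hull is built by randomized incremental insertion on
  deterministically jittered copies of the voxel centers (relative jitter
  `1e-7`), and facet offsets are then re-tightened against the unjittered
  points. For integer voxel-center geometry the smallest nonzero
  point-to-plane distance is far above the `1e-6` membership tolerance, so
  boundary voxels are always counted inside and genuinely outside voxels
  never are. Hull voxel counting uses the per-column interval form of the
  facet inequalities (exact, and linear in facets times columns).
* Degenerate inputs fail loudly everywhere (empty masks, coplanar hulls,
  constant features in Spearman, zero within-variance t-tests, all-zero
  table margins); the pipeline's policy is skip-and-log, never impute.
* The Spearman p-value uses the `t`-approximation with `n - 2` df
  (tie-corrected coefficient); an exact permutation p-value is available
  for `n <= 10`. The t-test is pooled-variance by default with Welch behind
  a flag. The chi-square test is Pearson without continuity correction,
  falling back to Fisher's exact test when any expected count is below 5 —
  the recorded `test_name` says which ran. No multiple-testing correction
  enters the screening decision; a Benjamini–Hochberg column is emitted
  alongside as a labeled extension.

## Problem sizes used in the shipped checks

Simulation-based checks run at sizes chosen to exercise the statistics
while staying desk-scale: direction recovery uses 10 cohorts of 50 lesions
per class (36³ grids); the permutation-null calibration uses one cohort of
15 per class with 20 label permutations; oracle-equivalence suites use
hundreds of arrays up to 6×6×5 where brute-force enumeration is exact.

## Known limitations

* Solidity/extent are voxel-count ratios and ignore anisotropic spacing
  (eccentricity does not); with 3 mm slices all three shape features are
  coarser than the in-plane resolution suggests.
* The GLSZM feature set follows the standard 11-feature vocabulary; no
  IBSI-compliance certification is claimed — conventions are documented
  instead.
* `best_k` selected by maximum LOOCV accuracy is optimistically biased as
  an estimate of the operating point at that `k`; a nested selection loop
  is deliberately out of scope.
* The phantom classes are homogeneous and well separated; use
  `class_params()` to build harder, overlapping cohorts when stress-testing
  the classifier stage.
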