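# bcsradiomics

Radiomic prediction of surgical re-excision after breast conservation
surgery (BCS) from dynamic contrast-enhanced breast MRI.

About 17–40% of breast-conserving surgeries are followed by a re-excision
because pathology finds tumor at or near the inked specimen margin — the
rate is highest for HER2-overexpressing cancers. This package implements,
as a tested and reusable R pipeline, the quantitative-imaging approach to
predicting that outcome before surgery: from a tumor volume contoured on
the first post-contrast T1-weighted series (and mapped to the pre-contrast
and two further post-contrast series), it extracts 87 features and
evaluates how well they separate lesions that needed re-excision from those
that did not.

## The method

**Features** (per lesion, with the contour shared across the four
timepoints `pre`, `post1`, `post2`, `post3`):

| family | features | count |
|---|---|---|
| shape (mask only) | solidity, extent, eccentricity | 3 |
| histogram (x4 scans) | minimum, median, mean, variance, skewness, kurtosis | 24 |
| GLCM (x4 scans) | energy, entropy, homogeneity, contrast | 16 |
| GLSZM (x4 scans) | SZE, LZE, LIZE, HIZE, LISZE, HISZE, LILZE, HILZE, GLN, ZSN, ZP | 44 |

Solidity is the voxel-count ratio of the lesion to its 3D convex hull;
extent the ratio to its tight bounding box; eccentricity
`sqrt(1 - lambda_min/lambda_max)` of the spacing-scaled covariance of the
voxel cloud. Texture features are computed on in-mask intensities quantized
to 16 equal-width levels per scan; the GLCM pools the 13 unique 3D
directions at distance 1, and GLSZM zones are 26-connected equal-level
components.

**Statistics.** Each feature is screened univariately against the binary
endpoint with Spearman's rank correlation (positive `Rs` = larger values in
the re-excision group) and a two-sample t-test. The multivariate model is
an RBF-kernel SVM (`C = 1000`, `gamma = 0.005`) under leave-one-out
cross-validation: within each fold, features are ranked by the BW-ratio

    BW(j) = sum_k n_k (xbar_kj - xbar_j)^2 / sum_k sum_{i in k} (x_ij - xbar_kj)^2

on the training rows only, and models are trained on the top `k` features
for `k = 1..30`, yielding accuracy / sensitivity / specificity curves with
exact Clopper–Pearson 95% intervals.

Because patient MRIs are not distributable, the package ships a calibrated
synthetic phantom generator: two lesion classes differing in shape
convexity (solidity ~0.94 vs ~0.80), histogram skewness (left- vs
right-skewed) and texture correlation length, written as NIfTI volumes +
masks with a CSV manifest, fully reproducible from one seed.

## Worked example

```r
library(bcsradiomics)

cfg <- run_config(output_dir = tempfile("run"), n_per_class = 10,
                  grid_shape = c(32, 32, 32), seed = 7, verbose = FALSE)
run_simulate(cfg)            # 20 lesions as NIfTI + manifest.csv
feats <- run_extract(cfg)    # 20 x 87 feature table
cv <- run_analyze(cfg)       # univariate screen + LOOCV sweep + report
cv
#> LOOCV top-k sweep over k = 1..30
#> best k = 1: accuracy 1.000, sensitivity 1.000, specificity 1.000

u <- univariate_screen(feats)
subset(u, feature %in% c("pre.solidity", "pre.extent", "post2.skewness"),
       select = c(feature, rs, p_spearman))
#>           feature       rs   p_spearman
#> 1    pre.solidity -0.86711 7.503138e-07
#> 2      pre.extent -0.86711 7.503138e-07
#> 50 post2.skewness  0.86711 7.503138e-07
```

Negative `Rs` for solidity/extent says irregular, non-convex lesions go to
re-excision; positive `Rs` for post-contrast skewness says right-skewed
enhancement histograms do. On this small, well-separated phantom cohort the
cross-validated classifier is perfect at `k = 1`; on the default 50+50
cohort the sweep produces the familiar rising-then-flat accuracy curve
(`cv$curve`). The report bundle (`cv_curve.csv`, `selected_features.csv`,
`univariate.csv`, `run_manifest.json`) lands in `cfg$output_dir`.

The pipeline also runs from a shell:

```sh
Rscript inst/cli/bcsradiomics.R report --config run.yaml
```

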