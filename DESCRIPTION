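Package: bcsradiomics
Title: Radiomic Prediction of Surgical Re-Excision After Breast Conservation Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-MRI pipeline for predicting surgical re-excision after
    breast conservation surgery from dynamic contrast-enhanced breast MRI.
    Extracts 3D shape (solidity, extent, eccentricity), first-order histogram,
    gray-level co-occurrence matrix (GLCM) and gray-level size zone matrix
    (GLSZM) features from a contoured tumor volume across one pre-contrast and
    three post-contrast timepoints; screens features univariately (Spearman
    rank correlation, two-sample t-test) against the binary re-excision
    endpoint; and classifies lesions with a radial-basis-kernel support vector
    machine under leave-one-out cross-validation, ranking features inside each
    fold by the ratio of between-group to within-group sums of squares
    (BW-ratio) and sweeping the number of top-ranked features. A calibrated
    synthetic phantom-cohort generator produces labeled NIfTI lesion volumes so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
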