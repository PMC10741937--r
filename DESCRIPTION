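Package: segvar
Title: Inter-Reader Variability Analysis of Multi-Sequence MRI Lesion Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying inter-reader variability of 3D organ and
    lesion delineations on multiparametric MRI. Provides geometry-aware binary
    mask handling with NIfTI input/output, the four standard contour agreement
    metrics (Dice similarity coefficient, Jaccard index, Hausdorff distance and
    mean distance to agreement) computed on anisotropic voxel grids via an exact
    Euclidean distance transform, post-hoc union combination of per-sequence
    lesion contours, cohort-level aggregation into per-sequence and per-reader-pair
    summary tables, and a statistical layer (between-sequence t-tests, PI-RADS
    group comparisons, Spearman screening, multivariate logistic regression and
    two-sample power calculations). A calibrated synthetic multi-reader cohort
    generator and a semi-quantitative initial-area-under-the-gadolinium-curve
    (IAUCG) module allow the full pipeline to be exercised end-to-end without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
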