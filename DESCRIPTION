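Package: ProCaMap
Title: Prostate Cancer Risk Maps from Multiparametric MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds voxel-wise prostate cancer probability maps from
    co-registered multiparametric MRI (T2-weighted, diffusion, and dynamic
    contrast-enhanced parameter volumes). Zone-specific logistic tissue
    models are fitted from region-of-interest statistics with mixed stepwise
    term selection, applied voxel-by-voxel to normalized volumes, and
    binarized with volume-ratio-calibrated probability thresholds into
    lesion masks, including a dual-threshold rule for high-grade disease.
    Includes two-step normalized-mutual-information rigid registration with
    quality control, bespoke confusion-matrix rules for tumor-burden and
    per-lesion evaluation with volume bounds, Bland-Altman and
    threshold-swept ROC analyses, and a synthetic phantom generator that
    emulates prostate zonal anatomy, endorectal-coil bias, and lesions of
    known grade and volume so the full pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    glmnet,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, ImageAnalysis, Classification, Regression
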