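Package: wsimil
Title: Weakly Supervised Biomarker Prediction from Whole-Slide Images
    with Attention-Based Multiple-Instance Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for weakly supervised prediction of
    molecular biomarkers (e.g. microsatellite instability or BRAF mutation
    status) from hematoxylin-and-eosin whole-slide images. Provides slide
    tessellation into tiles of fixed physical edge length with tissue and
    blur quality control, Macenko stain normalization, pluggable tile
    encoders producing per-patient feature bags, an attention-based
    multiple-instance learning classifier with optional clinical-covariate
    fusion, an ImageNet-style tile-classifier baseline with mean pooling,
    patient-level stratified cross-validation with AUROC/AUPRC and
    threshold statistics, attention and Grad-CAM explainability, and a
    synthetic-data generator so the whole pipeline is testable without
    access to clinical cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
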