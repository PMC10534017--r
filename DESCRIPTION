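Package: mfcrad
Title: Multi-Feature-Combined Radiomics Modeling for Tumor Local-Failure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting local failure of early-stage
    lung tumors from pre-treatment CT: handcrafted 3D radiomic feature
    extraction (shape, intensity, histogram, GLCM, GLRLM, GLSZM) under
    fixed-bin-number discretization, deep feature extraction with a 3D U-Net
    encoder and global average pooling, fusion with clinical covariates,
    multicollinearity-based feature reduction, and evaluation of four model
    variants (clinical-only, radiomics-only, deep-learning, and
    multi-feature-combined) with three classifier backends under
    leave-one-out and Monte-Carlo cross-validation. Includes a synthetic CT
    phantom cohort generator with a configurable planted image-outcome effect
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    e1071,
    ranger,
    igraph,
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
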