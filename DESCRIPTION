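Package: conndiag
Title: Connectome-Based Diagnostic Modelling and Reproducible Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for diagnostic classification and
    reproducible-biomarker discovery from functional-connectome and
    anatomical features. Provides tangent-space embedding of
    symmetric-positive-definite connectivity matrices at a Riemannian
    geometric-mean reference, a twelve-family model zoo (classical linear,
    classical nonlinear and compact neural-network families) behind one
    training and scoring contract, an unbiased random hyperparameter search
    over frozen stratified splits, permutation feature importance with a
    label-permutation null and Benjamini-Yekutieli false-discovery control,
    cross-model consensus biomarker ranking, hyperparameter-landscape
    analysis, and external-cohort transfer with supervised domain
    adaptation. Synthetic cohorts with planted group differences make every
    stage testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Matrix,
    MASS,
    glmnet,
    e1071,
    randomForest,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
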