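Package: vmatqa
Title: Unsupervised Anomaly Detection for VMAT Treatment Plans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated physics plan review for volumetric modulated arc
    therapy (VMAT). Control points of a plan are digitized into binary
    multi-leaf-collimator aperture maps and dose-weighted intensity maps,
    and a multi-task convolutional autoencoder is trained on regular plans
    to reconstruct aperture shape and per-control-point dose.
    Reconstruction-error distances score unseen plans, with threshold
    calibration at zero false-negative rate. Vanilla, contractive and
    variational autoencoder baselines, a constrained synthetic plan
    simulator with labelled fault injection, and a cross-validated
    evaluation pipeline (ROC/AUC, precision, FPR, F1) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
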