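Package: errpfusion
Title: Multi-Domain EEG Feature Fusion for Error-Potential Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detection of error-related potentials (ErrP) in multi-channel
    EEG. Implements the full pipeline: band-pass filtering, common average
    referencing and epoch extraction; level-1 features from the temporal
    domain (lagged correlation and covariance against class-mean templates),
    the spectral domain (empirical mode decomposition, Hilbert analytic
    signal and instantaneous-frequency statistics) and the spatial domain
    (common spatial patterns); two stages of neural-network dimensionality
    reduction collapsing per-channel features to per-domain posterior
    probabilities; and a final feed-forward classifier. Includes a seeded
    synthetic ErrP session simulator, ROC/AUC and confusion-matrix
    evaluation, per-subject AUC tables, an electrode-ablation study, CSV
    readers and writers for epoch and continuous-recording files, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
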