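Package: fedecg
Title: Explainable Federated LSTM Simulation for ECG Fiducial Features
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates privacy-preserving federated averaging (FedAvg)
    training of a stacked LSTM classifier on tabular ECG fiducial features
    (heart rate, wave amplitudes, and P-QRS-T intervals) for three-way
    classification of arrhythmic, healthy, and ischemic heartbeats.
    Provides a class-conditional synthetic cohort generator with
    Dirichlet-based non-IID client sharding, per-client SMOTE rebalancing,
    a from-scratch LSTM with Adam/SGD training in compiled code, the full
    confusion-matrix metric suite with one-vs-rest ROC/AUC, federated
    k-fold cross-validation, and post-hoc model explanation by exact
    Shapley-value enumeration and LIME local surrogates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
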