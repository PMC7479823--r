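Package: radER
Title: Delta-Radiomics Response Prediction with Pareto-Optimal SVM
    Ensembles and Evidential-Reasoning Fusion
Version: 0.1.0
Authors@R:
    person("radER", "Maintainers", email = "rader@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for early prediction of immunotherapy
    response from paired (baseline and post-cycle-1) 2D CT lesion images:
    intensity, gray-level co-occurrence texture, and geometry feature
    extraction with delta features; z-score normalization, Welch t-test
    screening and cross-correlation redundancy filtering; joint feature
    subset and RBF-SVM hyperparameter search by an iterative
    multi-objective immune algorithm yielding a Pareto-optimal model set;
    and evidential-reasoning fusion of the model set's probability
    outputs into a single calibrated prediction. Includes a synthetic
    cohort generator (lesion phantoms with a pseudoprogression subtype)
    so every stage is testable without patient data, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
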