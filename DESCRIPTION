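Package: inflaPD
Title: Turnover-Model Pharmacodynamics of the LPS-Stimulated Cytokine
    Cascade and Its Inhibition by Baicalein
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and pooled maximum-likelihood estimation for a
    semi-mechanistic indirect-response (turnover) model of the
    LPS-stimulated inflammatory cascade in RAW264.7 macrophages:
    zero-order TNF-alpha production with log-linear inhibition by
    baicalein, and delayed TNF-alpha-driven turnover of IL-6, iNOS
    expression and NO. Includes a synthetic-data generator matching the
    four-arm time-course design, residual-error models (additive,
    proportional, power), multi-start fitting with information criteria
    and CV% uncertainty, simulation-refit parameter-recovery studies,
    and goodness-of-fit / visual-predictive-check diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
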