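Package: nevusdyn
Title: Clonal Dynamics and Collective Growth Arrest of Melanocytic Nevi
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stochastic and analytic models for asking how benign melanocytic
    nevi stop growing. Implements cell-autonomous arrest models (single- and
    multi-stage Galton-Watson branching with per-cycle arrest probabilities,
    the exact Catalan-number total-progeny distribution and its 3/2 power-law
    tail, threshold searches and truncation sweeps), a collective
    renewal-control model in which the probability that daughters keep
    dividing falls with the number of arrested cells through a Hill function
    (stochastic ensemble and mean-field ODE forms), a minimal Cellular Potts
    agent-based model with a diffusing, decaying arrest signal secreted by
    arrested cells, summed-log2 gene-signature scoring of clustered
    single-cell expression data, and a within-field area-permutation test on
    nest neighborhoods with percentile envelopes. Synthetic-data generators
    provide ground-truthed inputs for every analysis stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    deSolve,
    Matrix,
    nortest,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    SingleCellExperiment,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
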