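Package: panet
Title: Regularized Partial-Correlation Network Analysis for Mixed Questionnaire Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and analysis of Gaussian graphical models from
    mixed-type (ordinal, binary, continuous) questionnaire data. Provides
    nonparanormal SKEPTIC and automatic mixed (Pearson, polychoric,
    polyserial) correlation estimation, graphical lasso fitting with
    Extended Bayesian Information Criterion (EBIC) model selection,
    weighted centrality indices and local/global clustering coefficients,
    case-dropping bootstrap stability (CS-coefficient) and edge-weight
    accuracy bootstraps, permutation-based network comparison tests, an
    iterative random-forest imputer for item-level missingness, and a
    synthetic questionnaire generator with known ground-truth network
    structure for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    mvtnorm,
    ranger,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
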