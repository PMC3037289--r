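Package: netprog
Title: Network-Based Cancer Prognosis with Higher-Order Module Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene-coexpression networks (soft-thresholded
    absolute correlation, topological overlap dissimilarity, average-linkage
    module detection), summarises modules by principal components, and expands
    them into four nested sets of representative features: first principal
    components only, per-module top components explaining a target fraction of
    variance, and either set augmented with quadratics and pairwise
    interactions. Fits Cox proportional-hazards models to these features by
    threshold gradient directed regularization (TGDR), including a modified
    variant enforcing strong heredity so that selecting a product term forces
    selection of its parent components. Prediction is evaluated by
    cross-validated risk scores, median-split logrank statistics and Harrell's
    concordance index. A block latent-factor simulator generates
    module-structured expression with Cox-model survival and calibrated
    censoring so the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    survival,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
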