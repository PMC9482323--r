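Package: epimediate
Title: Bidirectional Mediation Analysis for DNA Methylation and Allergic
    Sensitization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether DNA methylation changes are a cause or
    a consequence of allergic sensitization in longitudinal birth-cohort data.
    Implements counterfactual single-mediator causal mediation with
    quasi-Bayesian effect decomposition (average causal mediation effect,
    average direct effect, total effect, proportion mediated), methylation and
    polygenic risk scores with pruning-and-thresholding marker selection, and
    three high-dimensional mediator-nomination strategies: the
    divide-aggregate composite-null test with empirical-null calibration, sure
    independence screening followed by minimax-concave-penalty selection and
    joint-significance testing, and a gene-based test on kernel principal
    components. A seeded synthetic-cohort generator with planted mediation
    paths in both causal directions supports end-to-end testing with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
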