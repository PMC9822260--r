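Package: heritime
Title: Inheritance-Matrix Models of Interdivision-Time Correlations on
    Lineage Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generative modelling and Bayesian inference of interdivision-time
    correlation patterns on single-cell lineage trees. Hidden heritable cell
    cycle factors propagate from mother to daughter through a linear
    inheritance matrix with correlated sister noise; the stationary solution
    yields a generalised tree correlation function over family relations
    (mother-daughter, sister, cousin, ...). The package simulates binary
    lineage trees, estimates correlations with bootstrap errors by
    enumerating related cell pairs, classifies aperiodic, alternator and
    oscillator correlation patterns from the inheritance-matrix eigenvalues,
    recovers aliased oscillator periods compatible with an observed
    correlation oscillation, and fits the model to summary statistics by
    adaptive Metropolis-within-Gibbs sampling with AIC model comparison.
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
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
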