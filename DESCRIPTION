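Package: covrn
Title: Covariance Reaction Norm Models for Context-Dependent Life-History
    Trade-Offs
Version: 0.1.0
Authors@R:
    person("covrn", "developers", email = "covrn@example.org", role = c("aut", "cre"))
Description: Bivariate hierarchical models in which the correlation between
    two vital-rate traits is itself a regression, on the inverse hyperbolic
    tangent scale, of environmental covariates ("covariance reaction
    norms").  Supports repeated-measures, non-repeated-measures and hybrid
    sampling designs with Gaussian, Poisson and cumulative-logit ordinal
    traits, fitted by a built-in No-U-Turn Hamiltonian Monte Carlo sampler.
    Includes closed-form decompositions of observation-level correlations
    into among- and within-individual parts weighted by repeatability, an
    individual-based demographic simulator for validation by parameter
    recovery, posterior predictive checks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    readr,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    mvtnorm,
    numDeriv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
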