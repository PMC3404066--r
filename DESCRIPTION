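Package: aedesflux
Title: Water-Flux Covariates and Zero-Inflated Poisson Mixed Models for
    Container Mosquito Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal entomologic surveys of Aedes aegypti
    immatures in household water-storage containers. Builds water-flux
    covariates (>=20 percentage-point changes in stored volume between
    consecutive surveys), computes survey descriptives (positivity tables,
    per-house pupal means, flux event rates), fits a Bayesian two-level
    zero-inflated Poisson mixed-effects model with container- and
    household-level random effects in both model components by adaptive
    Metropolis-within-Gibbs MCMC, compares fixed-effects Poisson, negative
    binomial and zero-inflated Poisson fits via AIC and the Vuong statistic,
    and simulates synthetic surveys with the study's hierarchical structure
    for end-to-end testing and parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
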