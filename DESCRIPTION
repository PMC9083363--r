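Package: speedmix
Title: Bayesian Mixture Modeling of Rapid Guessing from Responses and
    Response Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a mixture hierarchical model that separates solution
    behavior from rapid guessing on speeded tests, using item responses
    together with response times. Solution-behavior responses follow a
    two-parameter logistic model with lognormal response times; rapid
    guesses succeed with an item-specific probability and share a common
    lognormal time distribution. Estimation is by a Polya-gamma augmented
    Gibbs sampler with Metropolis-Hastings updates for the constrained
    person covariance. Includes DIC and CPO/LPML model assessment,
    Gelman-Rubin convergence diagnostics, posterior summaries with highest
    posterior density intervals, and a simulator for speeded-test data
    with a time-limit-induced rapid-guessing mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
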