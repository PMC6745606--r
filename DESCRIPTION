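Package: defaultprior
Title: A Default Shrinkage Prior for Regression Coefficients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for Bayesian inference about a single regression
    coefficient under the default shrinkage prior N(0, g * se^2), where se
    is the standard error of an approximately normal, unbiased estimator.
    Provides the exact conjugate posterior, sign probabilities, credible
    intervals, and the conditional coverage of the standard Wald interval;
    folded-normal diagnostics quantifying magnitude exaggeration under the
    flat prior (type M error); a bound on sign evidence over symmetric
    unimodal priors (type S error); a numerically computed Jeffreys prior
    for the magnitude under a sign-mixture parameterization; and an
    empirical-Bayes Gamma mixed model that estimates the variance ratio g
    from collections of published two-sided p-values. Includes a synthetic
    data generator for the hierarchical model and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
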