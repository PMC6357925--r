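Package: pvligt
Title: Prospect Valence Learning Modelling of the Iowa Gambling Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the Iowa Gambling Task with the standard four-deck
    payoff schedule, implements the Prospect Valence Learning choice model as
    a generative agent and as a likelihood, estimates its four parameters per
    subject by hierarchical Bayesian MCMC or multi-start maximum likelihood,
    generates synthetic two-group cohorts at configurable group-level
    parameter and covariate distributions, and runs the covariate-adjusted
    group comparisons, nonparametric tests and bootstrapped correlations used
    to compare a high-risk group with controls.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
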