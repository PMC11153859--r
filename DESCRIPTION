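Package: valuelink
Title: Hierarchical Modelling of Value Learning and Value-Driven Visual Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for computational analysis of associative value learning
    and value-driven visual search. Implements a dual-learning-rate
    Rescorla-Wagner model with softmax choice, a Wiener first-passage-time
    (drift-diffusion) likelihood for two-choice response times, hierarchical
    Bayesian estimation of both models by adaptive Markov chain Monte Carlo
    with split R-hat diagnostics and posterior predictive checks, and
    cross-model linking analyses (posterior modes, Spearman rank
    correlations, learning curves). Includes deterministic, seedable task
    schedule generators and a synthetic-cohort simulator with known ground
    truth so every inference stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
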