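Package: ietmix
Title: Exponential Mixture Models for Inter-Event Times with MDL Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits mixtures of exponential distributions to inter-event times
    from time-stamped human-behaviour event streams, using the EM algorithm
    with broad log-uniform initialization and random restarts, and selects the
    number of components with six criteria: AIC, BIC, their
    latent-variable-completed versions, the normalized-maximum-likelihood
    codelength with latent variable completion and the decomposed NML
    codelength, including exact parametric-complexity recursions for the
    completed exponential mixture and the multinomial assignment model.  Also
    provides Pareto maximum-likelihood and KS-minimizing power-law tail
    (PLFit) baselines with truncated-likelihood comparisons, preprocessing of
    raw event streams into inter-event-time sequences, and seeded synthetic
    generators including state-switching Poisson processes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
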