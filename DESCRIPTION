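Package: occuVB
Title: Variational Bayes Inference for Single-Season Occupancy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian single-season site-occupancy models with logistic
    links for occupancy and conditional detection probabilities using two
    deterministic variational approximations: a Laplace-approximated
    coordinate-ascent scheme and a tangent (quadratic-bound) scheme with
    closed-form Gaussian updates. Maximum-likelihood and data-augmentation
    MCMC reference fitters, an L1 posterior-accuracy statistic, the
    posterior-predictive distribution of the number of occupied sites (PAO),
    a synthetic-data generator, and a replicated simulation-study harness
    for coverage and interval-width comparisons are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
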