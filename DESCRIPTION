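Package: caew
Title: Covariate Association Eliminating Weights for Causal Effect Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates covariate association eliminating weights (CAEW) for
    causal treatment effect estimation with treatments of arbitrary type
    (binary, categorical, normal, Poisson, semicontinuous two-part).  Weight
    constraints are obtained by inverting the weighted score equations of a
    chosen propensity function model at parameter values indicating no
    covariate-treatment association, and minimum-variance nonnegative weights
    are found by quadratic programming.  Includes maximum-likelihood
    stabilized inverse-probability-of-treatment weights as a baseline,
    weighted negative binomial outcome regression for marginal structural
    models, balance diagnostics based on weighted refitting, a longitudinal
    (pooled unit-interval) extension, synthetic data generators, and a
    simulation-study harness comparing the two weighting approaches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    quadprog,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
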