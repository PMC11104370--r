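Package: sctrnnpb
Title: Stochastic Continuous-Time Recurrent Networks with Parametric Bias
    for Simulating Autism-Like Developmental Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Implements the stochastic continuous-time recurrent neural
    network with parametric bias (S-CTRNNPB), a hierarchical predictive-coding
    model trained by minimizing a precision-weighted prediction error (Gaussian
    negative log-likelihood), with exact backpropagation-through-time gradients
    in compiled code.  Provides the experimental machinery around the model:
    synthetic emotion-structured multivariate sequences, condition grids over
    inter-level connection proportion (a model analogue of functional
    connectivity) and neural-excitability homogeneity, identity-blocked
    cross-validated training and parametric-bias-only recognition, an emotion
    recognition index (average silhouette width in parametric-bias space),
    mechanism analyses contrasting top-down and sensory-driven generation, and
    a synthetic-cohort pipeline that maps simulation conditions to
    imaging-defined subject subgroups and tests association with diagnosis and
    symptom scores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
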