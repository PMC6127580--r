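Package: animalgibbs
Title: Bayesian Linear and Threshold Animal Models via Gibbs Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits single-trait linear and threshold (liability) animal
    models and bivariate linear-threshold models to pedigreed data by Gibbs
    sampling, with flat priors on location effects and variance components.
    Builds Wright's numerator relationship matrix and its sparse inverse
    (Henderson/Quaas rules with inbreeding), estimates heritabilities and
    genetic correlations with equal-tail credible intervals, monitors
    convergence with the Geweke diagnostic and the Monte Carlo error, and
    compares models with DIC and harmonic-mean Bayes factors. Includes a
    synthetic-data generator (gene dropping on simulated pedigrees) so the
    full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    coda,
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    truncnorm,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
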