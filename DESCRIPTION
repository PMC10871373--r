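Package: neurochron
Title: Striatal Dopamine Dynamics and Human Interval Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of the coupling between striatal
    dopamine dynamics measured by fast-scan cyclic voltammetry and human
    temporal bisection performance.  Provides a synthetic-data generator
    with known ground truth (voltammetric calibration sets, 10 Hz session
    recordings with tonic drift and stimulus-locked transients, and
    bisection responses from a cumulative-Gaussian observer), an
    elastic-net concentration decoder, tonic/phasic signal decomposition,
    maximum-likelihood psychometric fitting (bisection point, JND, Weber
    fraction), cluster-based permutation tests of event-locked
    timeseries, mixed-effects trial-level models, Bayesian prevalence
    estimation and Bayes factors, composed into a reproducible seeded
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    lme4,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
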