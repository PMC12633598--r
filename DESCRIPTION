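Package: vkfbandit
Title: Volatile Kalman Filter Modelling of Restless-Bandit Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and latent-state modelling of behaviour in restless
    multi-armed bandit tasks. Provides generative task schedules with
    step-random-walk reward probabilities, trial-by-trial learning models
    (Rescorla-Wagner, Kalman filter, and the binary volatile Kalman filter
    with softmax choice rules), model-free behavioural metrics, hierarchical
    Bayesian model fitting with exceedance-probability model comparison,
    parameter-recovery and sensitivity harnesses, latent-trajectory
    adaptation analysis (linear and exponential fits), and bootstrap
    mediation analysis linking uncertainty adaptation to questionnaire
    outcomes in two-group designs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    withr,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
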