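Package: cwcst
Title: Parallel Reinforcement-Learning Models of Card Sorting Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and trial-by-trial cognitive modelling of the
    computerized Wisconsin Card Sorting Test (cWCST). Provides the task
    engine (24-card deck, category-switch schedule, session loop for
    arbitrary agent policies), weighted-parallel (wP-RL), parallel (P-RL)
    and model-based-only (MB-RL) reinforcement-learning models plus the
    attentional-updating (AU) benchmark, per-subject maximum-likelihood
    and hierarchical Bayesian estimation with probit-transformed
    non-centered parameterizations, K-fold cross-validated predictive
    model comparison (elpd), one-trial-ahead posterior-predictive
    simulation, synthetic-cohort generation, and behavioral scoring of
    perseveration and set-loss errors stratified by response demand.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, graphics, grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
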