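Package: prlearn
Title: Probabilistic Reversal Learning: Task Simulation, Reinforcement
    Learning Model Fitting and Behavioural Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying reward-guided learning in probabilistic
    reversal tasks of the kind used in human neuromodulation experiments.
    Provides a generator for the three-symbol reversal task (stochastic
    70/30 reward schedule, covert contingency reversals every 25 trials,
    fixed pair rotation), Rescorla-Wagner reinforcement-learning agents
    with symmetric or valence-asymmetric learning rates, maximum-likelihood
    fitting by grid search plus Nelder-Mead simplex refinement (with an
    analytic observed-choice likelihood and a simulation-based
    predicted-choice-probability likelihood), BIC model comparison, and the
    accompanying behavioural statistics: win-stay regression with
    condition-level ANOVA and paired post-hoc tests, block-wise contrasts,
    smoothed learning curves, mixed-model contrasts on high-probability
    choice, maladaptive win-stay rates, exploratory performance metrics and
    rank tests. Synthetic multi-subject cohorts with injected condition
    effects support parameter-recovery, model-recovery and statistical
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    lme4,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
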