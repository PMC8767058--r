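Package: twostepr
Title: Simulation, Hierarchical Fitting and Group Analyses for the Two-Step
    Decision Task
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the two-step sequential decision task: task
    simulation with drifting reward probabilities, a seven-parameter hybrid
    model-free/model-based reinforcement-learning agent, per-subject maximum
    a posteriori estimation with hierarchical empirical-Bayes expectation
    maximization and Laplace approximation, integrated-BIC model comparison,
    scoring of the Blatant and Subtle Prejudice Scale, and the group-level
    inferential analyses linking questionnaire scores to the balance of
    model-free versus model-based control (stay-switch mixed-effects
    logistic regression, second-stage reaction-time models, and parameter
    regressions with semipartial R-squared effect sizes). Includes a
    synthetic-cohort generator with a known planted association for
    end-to-end validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
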