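Package: twostepr
Title: Two-Step Task Simulation and Hybrid Reinforcement-Learning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for the two-step (Markov
    decision) task used to dissociate model-based from model-free
    reinforcement learning. Provides the task environment (80/20 transition
    structure, reflected Gaussian random-walk rewards on a -4..+5 point
    scale, pre-simulated walk selection favouring model-based play), a
    hybrid SARSA(lambda) dual-system agent with softmax choice and
    perseveration, per-session maximum a posteriori parameter estimation
    with BIC and optimal-choice-rate diagnostics, model-agnostic stay
    probability scores (MF-score, MB-score), paired session statistics
    with default-prior Bayes factors, Widmark/Watson alcohol dosing
    arithmetic, and a synthetic crossover-cohort generator with a
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
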