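Package: selfprior
Title: Bayesian Observer Analysis of Goal-Directed Action Perception
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for visuomotor "Stop" tasks
    probing the perception of action outcomes. Simulates per-trial behavioral
    data from a Gaussian cue-integration observer with an optimistic prior
    centered on the action goal, applies trial- and subject-level exclusion
    rules, fits two Bayesian observer models per subject by maximum
    likelihood with BIC model comparison, derives normalized prior width and
    prior accuracy, and runs the group-level statistics (t-tests, exact sign
    test, type-III ANCOVA, Spearman and partial Spearman correlations with
    Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
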