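Package: coopgaze
Title: Utility Models and Gaze-Sequence Analysis of Cooperation in One-Shot
    Prisoner's Dilemma Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how attention and payoff structure shape
    cooperation in one-shot Prisoner's Dilemma games. Generates the complete
    set of 96 payoff matrices on a 0-40 point grid, builds counterbalanced
    two-block sessions with four option-position conditions, and maps payoffs
    to screen areas of interest (AOIs). Implements a softmax utility model of
    cooperation combining other-regarding preference, belief about the
    opponent, and risk curvature, together with ten alternative
    specifications, maximum-likelihood fitting, and BIC model comparison with
    parameter-recovery diagnostics. A synthetic-cohort generator produces
    model-driven choices and fixation sequences with calibrated first-fixation
    biases and reading-order saccade transitions; feature extraction turns
    fixation tables into relative dwell times and fixation-slot encodings; and
    a leave-one-subject-out decision-tree classifier predicts trial-by-trial
    cooperation against a label-permutation chance level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
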