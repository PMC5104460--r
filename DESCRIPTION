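Package: infoseek
Title: Normative and Parametric Models of Costly Information Sampling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing behaviour in a two-option card game in which
    players pay escalating costs to reveal cards before gambling on the winning
    row. Provides an exact Markov-decision-process model of the game and its
    backward-induction (dynamic programming) solution; three summary statistics
    quantifying approach-related biases in information sampling (positive
    evidence approach, rejecting unsampled options, sampling the favorite) with
    gameplay-level bootstrap confidence intervals; reduced and full softmax
    choice models with multi-start fitting, k-fold cross-validation and an
    empirical-Bayes hierarchical population fit; a Pavlovian approach-avoidance
    model of a companion risky-choice task with median-split analysis; and a
    synthetic agent-population generator so that every stage of the pipeline
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
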