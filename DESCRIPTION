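Package: beadstask
Title: Graded-Estimates Beads Task: Ideal-Observer Scoring and
    Marginal-Model Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the graded-estimates (GE) variant of the beads task
    used to study probabilistic reasoning and the jumping-to-conclusions
    bias in schizophrenia. Builds the canonical two-ratio (80:20, 60:40),
    two-content (neutral beads, emotional faces) task design; computes exact
    Bayesian ideal-observer posterior trajectories; converts slider
    responses to the 0-10 scale and scores each trial by its absolute
    deviation from the normative model; simulates synthetic
    patient/control cohorts with clinical scores linked to biased-observer
    parameters through a Gaussian copula; and fits population-averaged
    (GEE-style) marginal models with exchangeable working correlation and
    robust sandwich standard errors, with least-squares means, group
    contrasts, symptom correlations, and demographic comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    truncnorm
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
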