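Package: vbdm
Title: Adaptive Value-Based Decision-Making Battery and Informative-Prior
    Bayesian Analysis of Addictive-Disorder Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and estimates a four-task battery of impulsive
    decision-making (hyperbolic delay discounting, probability discounting
    for gains and losses, loss aversion in mixed gambles) with a grid-based
    adaptive Bayesian trial-selection procedure; generates a synthetic
    three-group longitudinal cohort (substance use disorder,
    non-substance-related addictive disorder, controls) with baseline and
    one-year follow-up severity indicators; and analyses group differences
    and one-year predictive associations with informative-prior Bayesian
    linear regression, directional posterior probabilities,
    precision-weighted normal combination, and reverse-Bayes prior
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
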