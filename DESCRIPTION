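Package: revlearn
Title: Bayesian Modelling of Cue-Based and Outcome-Based Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying hidden-state inference under volatility in a
    two-category reversal learning task that can be framed either as cue-based
    (observation) or outcome-based (action) inference. Generates task blocks
    whose stimulus evidence is exactly matched between the two framings via
    pre-generated tilts, simulates Bayes-optimal and noisy Bayesian observers,
    fits the observer's parameters (perceived hazard rate, inference noise,
    selection noise, lapses) by particle MCMC with Bayesian model selection,
    fits reversal and repetition psychometric curves, computes per-stimulus
    characteristics including the consistency of each stimulus with the
    ongoing belief, estimates the hazard rate that best explains a consistency
    code, and simulates populations of linear coding units to quantify the
    similarity of neural codes across conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
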