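Package: plaidpercept
Title: Population-Code Simulations and Priming-Curve Analysis for Global
    Motion Perception of Drifting Plaids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how a decision neuron could read out global
    motion direction of drifting plaids from populations of component and
    pattern cells, and to analyse the visual-priming psychophysics that
    probes this ability behaviourally. Provides Von Mises direction-tuned
    cell populations with cross-orientation suppression, an L2-regularized
    logistic decision-neuron readout with generalization curves over
    stimulus direction, decoding-pool pruning and homeostatic weight-norm
    analyses, a behavioural pipeline (trial validity filtering, learning
    curves, priming curves, priming-magnitude statistics, session-level
    bootstrap confidence intervals), a synthetic two-alternative
    forced-choice trial generator with known ground truth, and config-driven
    scenario recipes that reproduce each simulation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
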