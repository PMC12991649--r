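Package: tvatoj
Title: Hierarchical Bayesian TVA Modelling of Temporal Order Judgements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models temporal order judgement (TOJ) data with the Theory of
    Visual Attention (TVA): a closed-form exponential race psychometric
    function parameterized by processing capacity C and the relative
    attentional weight of the probe stimulus, hierarchical Bayesian
    estimation (via JAGS) of participant- and group-level parameters under
    shared-capacity and condition-specific-capacity model variants,
    Pareto-smoothed importance-sampling leave-one-out (PSIS-LOO) model
    comparison with pseudo-BMA+ and stacking weights, simulation-based
    Bayesian power analysis for TOJ designs, and self-prioritization effect
    scoring from shape-label matching data. Includes a synthetic-data
    generator emulating the statistical structure of TVA-TOJ experiments so
    the full pipeline can be exercised without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
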