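Package: operantSA
Title: Simulation and Phenotyping of Operant Drug Self-Administration
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A discrete-event engine for operant intravenous
    self-administration sessions in rodents (fixed-ratio and
    progressive-ratio schedules, foot-shock punishment tests, extinction,
    and cue-induced reinstatement), together with a stochastic
    behavioral-agent cohort simulator, an addiction-phenotyping layer
    (persistence, motivation/breaking point, compulsivity; 75th-percentile
    thresholding and the 2-of-3 addiction-criteria classification;
    extinction criterion and craving parameters), and the accompanying
    statistical toolkit (normality-gated two-group tests, Mann-Whitney U,
    chi-square, Pearson correlation matrices, mixed-design repeated-measures
    ANOVA with Fisher LSD, and varimax-rotated principal component
    analysis).
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
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
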