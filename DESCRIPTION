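Package: soundloc
Title: Simulation and Analysis of Sound-Localization Training Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing virtual sound-localization
    training experiments. Provides interaural-polar coordinate transforms and
    spherical sampling utilities, the four standard localization-error metrics
    (spherical angle error, lateral error, polar angle error, front-back
    confusion rate) with their eligibility gates and signed bias variants, an
    adaptive target-size staircase and a three-day training/testing protocol
    simulator driven by a parametric virtual-listener model, exponential
    learning-curve fitting with derived timescale summaries, and the
    group-level statistical analyses (paired t-tests, one-way ANCOVA with
    Tukey post hoc contrasts, trained versus untrained HRTF comparisons)
    that such studies report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
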