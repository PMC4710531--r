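Package: oocytedyn
Title: Oocyte Growth Dynamics and Fecundity Prediction for Fathead Minnows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual-based stochastic simulation of fathead minnow egg
    production driven by plasma vitellogenin (VTG). Batches of oogonia are
    recruited at truncated-lognormal intervals with truncated-lognormal
    clutch sizes, grow by absorbing plasma VTG according to a linear
    ordinary differential equation, and spawn on reaching a threshold
    volume. Includes the reproduction metrics of the standardized 21-day
    fish short-term reproduction assay (average fecundity, eggs per spawn,
    spawns per female, cumulative fecundity), same-day spawn binning for
    group spawning designs, Kolmogorov-Smirnov distribution comparison,
    text input/output formats, synthetic cohort generation and a
    command-line runner for replicated experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
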