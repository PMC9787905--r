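Package: pdgait
Title: Pressure-Insole Gait Analysis for Parkinson's Disease States and
    Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing bilateral pressure-insole gait recordings in
    Parkinson's disease studies: a synthetic recording generator with known
    ground-truth gait events, a hysteresis state-machine detector for the
    heel-strike / foot-flat / heel-rise / toe-off sequence, extraction of 18
    temporal and spatial gait features, MDS-UPDRS Part III severity binning,
    a linear mixed-model significance screen with Bonferroni adjustment, and
    a tree-ensemble classification bench (AdaBoost, Extra Trees, Random
    Forest) for group, medication-state and severity tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    ranger,
    rpart,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
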