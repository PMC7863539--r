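Package: boolimp
Title: Boolean Implication Analysis for Microbiome OTU Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers Boolean implication relationships between microbes in
    OTU count tables. Fits a per-microbe step-function threshold (StepMiner)
    to log2 abundances, discretizes samples into low/intermediate/high
    states, classifies every microbe pair into one of six Boolean
    implication relationship types using sparse-quadrant independence
    statistics (BooleanNet), estimates a permutation-based false discovery
    rate, nominates relationships that are invariant across datasets, and
    contrasts Boolean relationships with Pearson correlation. Ships a
    synthetic OTU-table generator with planted implication structure, a
    metadata differential-abundance helper, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
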