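Package: fidashift
Title: Flow-Induced Dispersion Analysis of Sphingosine 1-Phosphate
    Carrier Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models and analyses flow-induced dispersion analysis (FIDA)
    assays that measure how the signaling lipid sphingosine 1-phosphate
    (S1P) partitions between its plasma carriers, human serum albumin
    (HSA) and high-density lipoprotein (HDL). Simulates Taylorgrams from
    the Taylor-Aris dispersion model, fits them by nonlinear least
    squares to recover hydrodynamic radii via the Stokes-Einstein
    relation, fits binding isotherms to estimate dissociation constants,
    computes the carrier-shift statistic (the difference between the
    complex-dissociation and capillary-mix hydrodynamic radii), and runs
    a cohort analysis linking the shift to sepsis severity and outcome
    on synthetic patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'physics.R'
    'fitting.R'
    'binding.R'
    'carrierShift.R'
    'synthetic.R'
    'io.R'
    'fidashift-package.R'
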