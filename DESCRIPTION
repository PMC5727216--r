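Package: riboloop
Title: Ribosome Traffic, mRNA Looping and Length-Dependent Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modelling of transcript-length-dependent
    translation. Implements a kinetic Monte Carlo simulator of the
    exclusion process with extended particles (the l-TASEP) describing
    ribosome traffic on an mRNA, closed-form low-density-phase
    current/density relations, a Gaussian-chain polymer model of the
    polysome-dependent mRNA end-to-end distance (with optional
    circularisation), and a ribosome-recycling feedback on the initiation
    rate solved both analytically (fixed point) and by a self-consistent
    simulation scheme. Includes weighted nonlinear least-squares fitting
    of the feedback parameters to ribosome density versus CDS-length
    tables, resource-competition predictions, and a synthetic-data
    generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
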