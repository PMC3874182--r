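Package: smtrace
Title: Segmentation and Analysis of Single-Molecule Magnetic-Tweezers Extension Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for magnetic-tweezers bead-extension traces of
    DNA tethers interacting with recombinase (RecA/Rad51) nucleoprotein
    filaments. Implements greedy piecewise-linear segmentation of
    extension-versus-time curves with a residual-autocorrelation score, an
    exact dynamic-programming segmentation oracle for validation, pause-level
    and extension-per-nucleotide estimation with implied filament coverage,
    strand-exchange elongation-rate estimation from slope histograms with
    bootstrap uncertainty, and per-bead force calibration against the dsDNA
    overstretching transition. A seeded synthetic-trace generator emulates the
    experiments (binding, strand exchange, controls, calibration ramps) with
    ground-truth labels so that every stage is testable without laboratory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
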