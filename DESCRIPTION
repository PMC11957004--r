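Package: nanoporeQC
Title: Quality Control of Cell-Free DNA Samples by Solid-State Nanopore Size Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for internal-calibrator nanopore quality control
    of cell-free DNA (cfDNA) samples. Simulates ionic current-time traces of DNA
    translocation through glass nanopipettes, detects resistive-pulse events
    with a hysteresis threshold detector, fits multi-Gaussian mixtures to
    blockage-amplitude distributions to resolve target, marker and genomic-DNA
    populations, and estimates total target concentration via a 1 kbp internal
    marker (C_T = C_M * f_T / f_M) together with the percent-cfDNA qualification
    metric. Includes pore-diameter estimation from open-pore conductance and a
    multi-pore, multi-duration coefficient-of-variation analysis for
    measurement-uncertainty assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'pore_geometry.R'
    'trace_sim.R'
    'event_detect.R'
    'quantify.R'
    'mixture_fit.R'
    'pipeline.R'
    'uncertainty.R'
    'interface.R'
    'nanoporeQC-package.R'
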