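Package: evplex
Title: Multiplex Bead-Based Flow-Cytometry Analysis of Extracellular Vesicle Surface Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplex bead-based flow-cytometry assays of
    extracellular vesicle (EV) surface markers. Demultiplexes hard-dyed capture
    bead populations from their two dye-channel intensities, computes per-population
    median fluorescence intensity (MFI) signatures with matched-control background
    correction, normalizes across instruments via log10 sample/control ratios,
    estimates per-marker limits of detection from input titrations, and includes a
    seeded synthetic assay simulator (bead clusters, dose-dependent Langmuir
    capture, isotype-control background, doublets, instrument gain/spillover
    profiles) so every stage is testable without cytometer data. Reads and writes
    FCS 3.1 and a plain-text event table dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    yaml,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    jsonlite
Config/testthat/edition: 3
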