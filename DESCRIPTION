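Package: tripletRCS
Title: Triplet-Resolved Analysis of RNA-Catalyzed Rolling Circle Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding and quantitative analysis of primer-extension products
    made by a triplet polymerase ribozyme on small circular RNA templates.
    Provides triplet-frame segmentation of sequencing reads, barcode
    classification, prefix-conditioned per-position incorporation fidelity,
    cumulative templated-synthesis probabilities and circular-vs-linear fold
    differences, concatemer length spectra for branched rolling circle
    synthesis, gel-densitometry extension-efficiency statistics with
    helical-pitch periodicity detection, and a seeded synthetic-read and
    gel-lane simulator with ground-truth records for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
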