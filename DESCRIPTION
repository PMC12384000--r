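Package: CaMScan
Title: Calmodulin-Binding Motif Scanning and Domain Prediction in Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive enumeration and curated classification of canonical
    calmodulin-binding anchor-spacing motifs (1-10, 1-12, 1-14, 1-16, 1-5-10,
    1-8-13, 1-8-14) and IQ motifs in protein sequences, a sliding-window
    propensity predictor for candidate calmodulin-binding domains (CaMBDs),
    anchor-residue fingerprint comparison between proteins, and annotation of
    Tau (2N4R) phosphorylation and dephosphorylation sites onto scanned
    regions. Ships curated CaMBD peptide fixtures for Tau and its
    calmodulin-regulated kinases and phosphatase, and a seeded synthetic
    protein generator for predictor validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
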