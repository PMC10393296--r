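Package: ciliareg
Title: Regulatory Analysis of the C. elegans Ciliome Gene Battery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study transcriptional co-regulation of the C. elegans
    sensory ciliome. Models a curated cilium effector gene battery with its
    category structure, extracts promoters and scans them with position
    weight matrices, tests k-mer over-representation, annotates ChIP-seq
    peaks to genes under a strand-aware TSS window, prioritizes transcription
    factors by binding to the battery with regression-based outlier
    detection, computes central motif enrichment within peak windows and
    X-box-to-peak distance profiles, screens single-cell expression data for
    cell-class-enriched regulators, and tests genetic synergy between
    regulators under the multiplicative model with propagated error. A
    synthetic-data generator emulates every input with known ground truth so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
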