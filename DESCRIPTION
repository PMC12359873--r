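Package: scmethpipe
Title: Simulation, Calling and Analysis of Direct-Conversion Single-Cell
    5mC/5hmC Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for bisulfite-free single-cell DNA
    methylation and hydroxymethylation sequencing based on direct
    pyridine-borane conversion chemistry (TAPS and CAPS), in which the
    modified cytosine is the base that reads as thymine. Provides a
    chemistry-aware read simulator with barcoded Tn5 fragments and
    spike-in controls, an i5/i7 barcode demultiplexer, a
    direct-conversion methylation caller with end-trimming and mapping
    quality filters, spike-in conversion-rate and false-positive
    estimators, per-cell quality gating, coverage and saturation
    statistics, region-level quantification (gene bodies, fixed bins,
    metagene profiles), and clustering with marker detection on
    gene-body modification levels. All tabular results are tibbles so
    analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicAlignments,
    GenomicRanges,
    generics,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
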