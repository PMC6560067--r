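Package: m5Cpipe
Title: RNA Bisulfite Sequencing Analysis of NSUN2-Dependent m5C Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven implementation of an RNA bisulfite sequencing
    (BS-seq) analysis for 5-methylcytosine (m5C) in non-coding RNAs such as
    tRNAs and vault RNA VTRNA1.1. Provides a mini-reference data model, a
    bisulfite read simulator with complete ground truth, adapter trimming,
    three-pass conversion-aware alignment (genomic, CCA-tail rescue, and
    splice-junction alignment with genomic back-conversion), per-cytosine
    methylation extraction with non-conversion artifact read filtering, and
    methyltransferase-dependence site calling by Welch's t-test with
    Benjamini-Hochberg false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
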