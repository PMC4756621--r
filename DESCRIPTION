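Package: regbuildr
Title: Regulatory Annotation Toolkit: Methylation Calling, Motif
    Features and a Consensus Regulatory Build
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building nucleotide-resolution regulatory
    annotation from epigenomic evidence. Calls per-cytosine methylation
    states from bisulfite conversion counts with a three-component
    mixture model (two beta-binomials plus a discrete uniform) fitted by
    expectation maximization; scans genomic sequence with JASPAR-style
    position weight matrices, calibrates match scores against an
    empirical score null and filters at a single-tail p-value cutoff;
    consolidates per-cell-type genome-segmentation states and
    experimental peaks into consensus regulatory features with
    functional classes and per-cell-type activity flags; and annotates
    single-nucleotide variants falling inside binding motifs with
    information-content and score-change consequences. Includes seeded
    synthetic-data generators for all inputs and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
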