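Package: repbime
Title: Detection of Repetitive Extragenic Palindromes, RAYT Transposases
    and Bacterial Interspersed Mosaic Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the in-silico identification and characterization of
    repetitive extragenic palindromes (REPs), their cognate REP-associated
    tyrosine transposases (RAYTs), and composite bacterial interspersed mosaic
    elements (BIMEs) in gammaproteobacterial genomes. Provides a structural
    parser for the GT(A/G)G-headed imperfect palindrome architecture of REPs
    (strict and mismatch/bulge-tolerant modes), a conserved-residue motif
    classifier for RAYT proteins, discovery of inverted REP pairs flanking
    candidate transposase genes, mismatch-tolerant genome-wide REP copy
    counting, decomposition of REP clusters into BIME basic modules with
    inter-REP segment labeling, neighbor-joining phylogenies with
    Robinson-Foulds congruence testing of REP/RAYT coevolution, an ortholog
    substitution-rate contrast, and a synthetic-genome simulator with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    ape,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    rtracklayer,
    GenomicRanges,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
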