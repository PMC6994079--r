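Package: poolprimers
Title: Multiplex PCR Primer Pool Partitioning with Bit-Parallel
    Hybridization Analysis and Index-Free Genome Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for preparing large multiplex PCR experiments.
    Scores all inter- and intra-primer interactions by base-match score or
    nearest-neighbour Gibbs free energy using bit-plane sequence encodings,
    maps every primer onto a reference genome (FASTA or UCSC 2bit) in a
    single index-free pass to reconstruct amplicons and detect overlapping
    amplicons, and partitions primer pairs into a user-chosen number of
    subpools by randomized hill climbing so that strongly interacting or
    overlapping pairs never share a reaction. Degenerate (IUPAC) primers
    are supported throughout.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
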