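Package: barcodekit
Title: Design and Demultiplexing of Error-Tolerant DNA Sample Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates large sets of DNA sample barcodes of arbitrary length
    under user constraints (GC content, homopolymer and tandem-repeat limits,
    sequence complexity, forbidden motifs, secondary-structure and
    cross-hybridisation screens) with a guaranteed minimum pairwise Levenshtein
    distance, optionally computed with wildcard padding so the set tolerates
    insertions and deletions. Includes a k-mer-index-accelerated, quality-aware
    demultiplexer that assigns FASTQ reads back to barcodes by semi-global
    alignment, a read simulator with a parameterised
    substitution/insertion/deletion error model, and accuracy evaluation against
    simulation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    rlang,
    ggplot2,
    generics,
    withr,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
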