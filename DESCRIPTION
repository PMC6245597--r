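Package: blocksw
Title: Blocked Smith-Waterman Scoring for Long DNA Sequence Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Score-only Smith-Waterman local alignment of long DNA sequence
    pairs with affine gap penalties (Gotoh recurrences), computed in vertical
    blocks of configurable width with row buffers and inter-block boundary
    exchange so memory stays linear in the sequence lengths. Includes an
    a-priori integer-width overflow guard for 8/16/32-bit score ranges, a
    full-matrix reference engine, GCUPS benchmarking, FASTA input, a seeded
    synthetic DNA pair generator with controllable substitution and indel
    divergence, and a command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    withr,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
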