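Package: exomir
Title: Exosomal Small-RNA Quantification and Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for exosomal small RNA-seq: 3' adapter and
    quality trimming, strata-aware multi-mapping short-read alignment
    (mismatch-only, best-stratum reporting), fuzzy-window assignment of
    alignments to mature miRNA/piRNA annotations with fractional 1/n
    multi-map counting, spike-in and median-of-ratios normalization,
    negative-binomial Wald differential expression, sample-correlation
    clustering with label-association diagnostics, and delta-Ct / ANOVA
    statistics for qPCR verification. Includes a synthetic small-RNA
    library generator with machine-readable ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    MASS,
    ape,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    Rsamtools
Config/testthat/edition: 3
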