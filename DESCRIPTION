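Package: guidelib
Title: Design and Screen Analysis of Pooled CRISPR sgRNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end design of single-guide-RNA (sgRNA) libraries for any
    annotated genome: PAM-site scanning on both strands, interval-tree based
    region filtering and annotation scoring, an exact mismatch-tolerant
    off-target search with a rank-weighted specificity score, Doench-2014
    (Rule Set 1) and position-weight on-target scores, hierarchical ranking,
    ready-to-order oligo assembly with restriction-site exclusion and coverage
    enforcement, rejection-sampled non-targeting control generation, and the
    pooled-screen count analysis used to validate such libraries (regex-based
    guide counting from FASTQ, median normalization, control-centred log2
    fold changes, Wilcoxon gene tests, z-score functional classification).
    Deterministic toy-genome and screen-read fixtures with planted ground
    truth make the whole pipeline testable without downloads.
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
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
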