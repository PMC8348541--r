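Package: cregnet
Title: Cancer-Specific Enhancer Regulatory Networks from H3K27ac, HiChIP
    and Hi-C Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for defining tissue-specific
    enhancers from multi-sample H3K27ac peak files, calling super
    enhancers by the ranked-signal inflection rule, classifying
    topologically associating domain (TAD) boundary changes between two
    conditions into six categories, annotating HiChIP interaction loops
    by enhancer anchor overlap, and identifying enhancer target genes by
    combining loop evidence with differential expression. Ships a seeded
    synthetic-data generator with planted ground truth so every stage of
    the pipeline is testable end to end without external downloads. All
    user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
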