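Package: sctyper
Title: Marker-Specificity-Weighted Cell-Type Annotation for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated cell-type annotation of clustered single-cell
    RNA-seq data using specificity-weighted positive and negative marker
    genes. Gene expression is z-scored across cells, weighted by a min-max
    cell-type specificity score computed from a tissue's pooled marker sets,
    summarised into per-cell enrichment scores and per-cluster annotation
    scores, with an explicit "Unknown" rule for low-confidence clusters.
    Includes a gamma-Poisson simulator with logistic dropout for benchmarking,
    Wilcoxon rank-sum marker extraction, leave-one-cell-type-out unknown
    detection, and an SNV-burden classifier separating malignant from
    non-malignant cell populations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
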