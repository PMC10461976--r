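Package: lentimpra
Title: Enhancer Activity Analysis for Lentiviral Massively Parallel Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies enhancer activity from barcode-level lentiMPRA
    DNA/RNA counts, fits a two-component Gaussian background model to
    shuffled negative controls, calls significantly active enhancers with
    Bonferroni family-wise error control, estimates assay sensitivity from
    positive-control distributions, classifies temporal activity across
    differentiation time points, scans sequences for transcription-factor
    binding sites with exact p-values, selects 270-bp core enhancer
    regions, relates activity changes to linked-gene expression, and tests
    overlap enrichment against external peak sets. Includes a synthetic
    data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    S4Vectors,
    GenomicRanges,
    IRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
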