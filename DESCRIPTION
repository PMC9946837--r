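Package: dsbmut
Title: Activity-Induced DNA Break and Somatic Mutation Quantification at
    Neuronal Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline linking neuronal activity to DNA damage
    and somatic mutation. Implements UMI-consensus amplicon mutation-frequency
    estimation with young-median age normalization and robust (ROUT-style)
    outlier removal; sBLISS-style double-strand-break cut-site deduplication
    and quantification over a summit-centred regulatory-element landscape
    stratified by transcription-factor binding quartile; median-of-ratios
    count normalization with batch adjustment and fold-threshold inducibility
    tests; and a resampling null for target-gene downregulation in
    single-nucleus expression data. Seeded synthetic-data generators emulate
    every input so the full pipeline runs and validates without external
    downloads.
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
    IRanges,
    limma,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
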