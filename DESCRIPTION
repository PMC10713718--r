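Package: t3chrom
Title: Condition-Dependent Chromatin Analysis of Thyroid Hormone Action
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully tested pipeline for analysing hormone-dependent
    transcription-factor binding and chromatin state. Provides windowed
    island-style differential peak calling with Poisson nulls and FDR control,
    three-way classification of binding sites by hormonal condition
    (maintained, abolished, de novo), TSS-proximal/distal partitioning,
    replicate peak intersection, site-anchored signal heatmaps and average
    profiles with a center-notch statistic, count-based differential tests for
    ATAC accessibility and RNA expression, a direct-repeat (DR0-DR8) nuclear
    receptor response-element scanner with spacer enrichment, distance-resolved
    peak-to-gene association, knockout blunting classification, and a seeded
    synthetic-data generator that emulates the statistical structure of a
    thyroid hormone (T3) pituitary chromatin study for ground-truth recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
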