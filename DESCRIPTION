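Package: msccpipe
Title: Methyl-Sensitive Cut Counting Methylation Analysis and Expression Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies genome-wide CpG methylation from methyl-sensitive cut
    counting (MSCC) experiments, in which tag counts from a methylation-sensitive
    HpaII library and an inverse methylation-insensitive MspI library are combined
    into a per-CCGG-site methylation fraction. Provides coverage filtering,
    calibration against internal spike-in standards of known methylation fraction,
    promoter and CpG-island annotation with signed distance to the nearest
    transcription start site, region-stratified summaries of methylation change
    between conditions, filtering of differential-expression tables, and
    classification of genes into methylation-expression concordance classes.
    Includes a seeded synthetic-data generator that emulates the two-library
    Poisson count structure, spike-in standards, promoter-targeted methylation
    shifts and a differential-expression table with known truth labels, so the
    whole pipeline can be exercised and validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    tidyr,
    rlang,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
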