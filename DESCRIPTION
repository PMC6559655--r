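Package: rarecnv
Title: Rare Copy Number Variant Case-Control Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for rare copy-number-variant (CNV) case-control
    studies on SNP-array call sets: multi-algorithm consensus merging of raw
    CNV calls into stringent CNVs, array-metric and CNV-count sample quality
    control, genomic-context exclusion filters (centromere/telomere buffers,
    segmental-duplication and immunoglobulin overlap fractions), per-gene
    carrier association using the two-tailed Fisher exact test with
    conditional maximum-likelihood odds ratios and exact confidence
    intervals, pooled Benjamini-Hochberg FDR control, rare-CNV
    classification, stratified CNV burden tables, gene-set
    overrepresentation analysis, and a seeded synthetic-study generator
    with known ground truth for end-to-end validation.
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
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
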