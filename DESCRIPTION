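Package: methregion
Title: Region-Based Tests of DNA Methylation Change in Family Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based, region-level analysis of DNA methylation change and
    drug response. Builds gene regions from transcript start sites, summarises
    CpG methylation change per region, and tests region-outcome association
    under a kinship linear mixed model: a median methylation level test (MMLT,
    Wald) and a variance-component set test (SKAT) with unit or dosage-based
    Beta-density weights and mixture chi-square p-values (characteristic
    function inversion with a moment-matching fallback). Includes
    Benjamini-Hochberg FDR, genomic-control and stratified QQ diagnostics, and
    a synthetic family-cohort generator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    matrixStats,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    rtracklayer,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
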