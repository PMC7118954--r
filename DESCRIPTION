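Package: vbcall
Title: Virtual-Barcode Consensus Calling of Low-Allelic-Fraction SNVs in
    Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Panel-wide single-nucleotide variant calling for hybrid-capture
    cell-free DNA (cfDNA) sequencing at allelic fractions down to 0.1%,
    without exogenous unique molecular identifiers. Read pairs are clustered
    into "virtual families" keyed by fragment start, template length and
    strand; within-family consensus (the f value) suppresses stochastic
    read-level errors. Recurrent mutant-family-level artifacts are polished
    against a background database of per-site allelic-fraction distributions
    selected from a fixed candidate family by AIC/BIC/SSE/R rank scoring,
    and residual stochastic artifacts are removed by three fine-tuning
    filters (fragment-end distance, variant-singleton ratio with
    sample-level FDR control, and a binomial minimum-template threshold).
    Includes a seeded cfDNA read-pair simulator with a ground-truth ledger
    so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    VariantAnnotation,
    withr,
    optparse
Config/testthat/edition: 3
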