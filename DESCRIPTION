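Package: varscape
Title: Cohort Versus Reference Variant Landscape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the genetic variant landscape of a sequenced
    cohort against a reference population: hard filtering of multi-sample VCF
    call sets (depth, genotype quality, site quality, minor-read ratio),
    novelty annotation against a known-variant catalog, cohort quality control
    (Ti/Tv, Het/Hom, concordance), genome-binned variant-density hotspot
    detection with one-sided Fisher exact tests and gene association, and
    Fisher-exact enrichment of variant classes within regulatory feature sets
    (LD blocks, histone peaks, DNase hypersensitivity sites, CTCF sites,
    regulatory-potential score tracks). Includes a seeded synthetic-data
    generator so the whole pipeline is testable without external downloads.
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
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
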