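Package: ssrpopgen
Title: EST-SSR Mining, Diversity Statistics and DNA Fingerprinting for
    Codominant Microsatellite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for microsatellite (SSR) marker
    studies on diploid, codominant genotype data. Mines perfect and
    compound simple sequence repeats from transcript FASTA files with
    MISA-style thresholds and canonical motif classification; computes
    per-locus and per-population diversity statistics (Na, Ne, Shannon's
    I, Ho, He, unbiased He, fixation index, PIC); estimates Wright's
    F-statistics, gene flow and Nei's genetic identity and distance from
    allele frequencies; summarises population structure via UPGMA trees,
    principal coordinate analysis and the Evanno delta-K statistic; and
    selects a minimal PIC-ranked marker panel that uniquely fingerprints
    every accession, emitting QR-ready payload strings. A Balding-Nichols
    island-model simulator generates genotype matrices with known
    differentiation and inbreeding for validation and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
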