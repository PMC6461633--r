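Package: gclipidr
Title: Targeted Plasma Lipidomics of Glucocorticoid Excess
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for targeted (MRM/SIM) plasma lipidomics of
    short- and long-term glucocorticoid excess in dogs: parsing of lipid
    shorthand nomenclature, single-point internal-standard quantification of
    raw peak areas including an M+2 isotope-interference correction for
    sphingosine 1-phosphate, a pooled-QC exclusion cascade (area floor,
    blank ratio, %CV), paired before/after differential statistics on log2
    concentrations with Benjamini-Hochberg FDR, double-bond saturation-class
    aggregation, and descriptive multivariate outputs (PCA, Pearson/Ward
    clustering). Ships a seeded synthetic-experiment generator emulating the
    two-arm paired study design so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
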