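Package: dvtmark
Title: GWAS-Driven Prioritization of Blood-Based Biomarkers for Deep Vein Thrombosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, reproducible reimplementation of a post-GWAS gene
    prioritization workflow for deep vein thrombosis (DVT): genome-wide
    significance filtering of catalog associations, linkage-disequilibrium
    proxy expansion, a seven-criterion functional-annotation scorecard,
    hypergeometric gene-set over-representation with Benjamini-Hochberg
    false-discovery-rate control, gene-disease network filtering, and a
    whole-blood expression/eQTL biomarker selection rule. A synthetic-data
    generator emulates the catalog, LD panel, annotation, gene-set, network
    and expression resources with planted ground truth so the whole pipeline
    is testable without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
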