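Package: ssd
Title: Species Specificity and Specificity Diversity Analysis for Microbiome Data
Version: 0.1.0
Authors@R:
    person("SSD", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Quantifies host/habitat specificity of microbial taxa from
    abundance tables (species specificity, the product of prevalence and
    abundance share), aggregates specificity into Hill-number diversity
    profiles (specificity diversity), and provides permutation tests that
    catalogue unique and enriched taxa between treatments and compare
    assemblage-level specificity diversity. Also fits power-law models of
    specificity diversity against host phylogenetic timelines, builds
    FDR-controlled Spearman specificity-correlation networks, catalogues
    exclusively unique taxa via presence XOR, and ships seed-deterministic
    synthetic-data generators with planted ground truth plus a command-line
    pipeline for hierarchical comparison schemes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
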