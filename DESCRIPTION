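Package: pollenmir
Title: Cross-Kingdom Small RNA Profiling and miRNA Target Energetics for
    Honeybee Caste Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale reimplementation of the computational chain used to
    study plant microRNAs carried in honeybee larval food. Provides a
    synthetic small-RNA data generator with ground-truth labels, a dual-kingdom
    read census (adapter masking, length filtering, exact transcript
    assignment, miRBase-style mature matching with a terminus shift rule,
    normalization to a fixed library size), cross-sample miRNA profile
    comparison, an intermolecular RNA:RNA minimum-free-energy duplex model
    with nearest-neighbor thermodynamics, a weighted-complementarity target
    screen with seed mutagenesis, GO chi-square enrichment over an ortholog
    map, qPCR standard-curve and delta-delta-Ct quantification, phenotype
    group statistics, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
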