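Package: npcstand
Title: Coverage-Aware Standardization for Comparative Metagenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to demonstrate and correct biases caused by uneven
    metagenome diversity coverage in comparative metagenomics. Simulates
    metagenomes with controlled evenness, richness and microdiversity
    (log-normal species-abundance designs with enforced max/min ratios),
    estimates Nonpareil-style diversity coverage (Npc) from k-mer read
    redundancy curves fitted to a log-gamma model, standardizes
    feature-by-sample abundance tables (SD/GEQ, RPKM) to a common Npc,
    computes the maximum acceptable coverage difference per feature
    (delta-Npc-max), and evaluates richness and differential-abundance
    accuracy under equal versus unequal coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    vegan,
    jsonlite,
    minpack.lm,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
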