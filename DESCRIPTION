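Package: plantmir
Title: Plant Small RNA Cleaning, miRNA Discovery, Target Prediction and
    Stem-Loop Primer Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for plant microRNA analysis from
    small RNA sequencing libraries: adapter-aware read cleaning and tag
    collapsing, exclusion of non-miRNA ncRNAs, assignment of tags to known
    mature miRNAs within an edit budget, family grouping, quantification
    and conservation classification, hairpin-based novel miRNA discovery
    against a reference genome using a nearest-neighbour folding model,
    rule-based plant miRNA target prediction with G:U wobble scoring, and
    stem-loop RT-PCR primer design for validation assays. Ships a seeded
    synthetic-data generator with truth tables so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
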