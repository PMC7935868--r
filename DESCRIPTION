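Package: circsig
Title: Circular Plasmid Resolution and Engineering-Signature Annotation
    for Hybrid Yeast Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processes long-read assemblies of engineered yeast
    genomes: detects candidate circular contigs (assembler flags or
    tandem self-repeat structure), resolves collapsed tandem-multimer
    plasmid contigs to consensus circular monomers validated by
    junction-spanning reads, locates genetic-engineering signatures and
    genome features under explicit identity and query-coverage gates,
    classifies per-construct assembly failure modes, estimates plasmid
    and tandem-repeat copy numbers from read depth, reports
    telomere-to-telomere completeness, and plans sequencing coverage,
    dilution, and multiplexing.  A seeded synthetic-genome and read
    simulator makes every stage testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
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
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
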