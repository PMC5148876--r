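Package: endosig
Title: Comparative Genomic Lifestyle Signatures for Fungal Root Endophytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize the lifestyle of a fungal genome from
    comparative multi-species data: repeat-induced point mutation (RIP)
    dinucleotide fold-change analysis and sliding-window genome content
    tracks, repeat-candidate filtering, a horizontal gene transfer (HGT)
    screen based on taxonomic skew and bit-score dominance with greedy
    centroid clustering and neighbor-joining sister-clade calls,
    lifestyle-enrichment rules on ortholog presence/absence matrices with
    PCA placement, protein-domain (InterPro-style) Z-test and fold-change
    enrichment, CAZyme substrate-class profiling, and NRPS/PKS
    domain-architecture classification. A seeded synthetic-data generator
    emulates the multi-species inputs with planted signals so every stage
    can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
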