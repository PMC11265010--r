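Package: soilgv
Title: Marker-Gene Ecology of Soil Giant-Virus Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing soil giant-virus (nucleocytoplasmic
    large DNA virus, NCLDV) communities from a polB marker-gene survey:
    dereplication of marker sequences into phylotypes, placement-based
    identification and family-level taxonomy on a labeled reference tree,
    coverage normalization, habitat-occupancy and environmental-range
    (niche breadth) analysis, alpha/beta diversity with permutation-based
    inference (PERMANOVA, Mantel and partial Mantel tests, distance-decay,
    variation partitioning), virus-eukaryote co-occurrence networks under
    Benjamini-Hochberg false-discovery control, and screening of assembled
    contigs for putative giant-virus origin. A synthetic-data generator
    with recorded ground truth emulates habitat-structured communities so
    that every stage of the pipeline is testable without raw metagenomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    geosphere,
    jsonlite,
    phangorn,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
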