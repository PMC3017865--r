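Package: labsecretome
Title: Ortholog Clustering and Secretome Extraction for Lactic Acid Bacteria Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for building Lactobacillales-specific clusters of
    orthologous groups (LaCOGs) from bacterial proteomes and extracting the
    secretome subset. Orthology cores are built from bidirectional best hits
    of Smith-Waterman protein alignments, seed clusters are extended with the
    uniform top-3 rule, leftovers are swept up by an iterative distant-homolog
    search and finally classified as distant homologs or ORFans. Subcellular
    location is assigned by a rule-based signal-grammar classifier (or an
    external annotation table), secretome families are extracted by a
    majority vote over members, frameshifted pseudogene fragments are
    concatenated into full-length proteins and reassigned to families, and
    cluster presence/absence patterns are classified as ubiquitous, niche-,
    species- or strain-specific. A synthetic proteome generator with planted
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
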