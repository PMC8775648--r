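Package: histoparalog
Title: Detection, Classification and Evolutionary Analysis of Archaeal
    Histone Paralogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative genomics of archaeal histone-fold
    proteins: profile-matrix detection of histone candidates in predicted
    proteomes, physicochemical featurization (amino-acid class composition
    and isoelectric point) with reference-anchored principal-component
    classification into two ancient paralog groups, per-column diagnostic
    residue calling and sequence-logo information content, neighbor-joining
    gene trees with a reciprocal-monophyly test for ancient paralogy, Fitch
    and Dollo parsimony mapping of histone-type gains and losses on a
    species tree, and reciprocal-best-hit orthology with gene-neighborhood
    (synteny) comparison. Ships a seeded simulator that generates species
    trees, duplicated histone families with group-diagnostic residues,
    conserved gene neighborhoods and decoy proteins, together with
    ground-truth tables, so that every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    seqinr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
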