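Package: genefambd
Title: Birth-and-Death Reconstruction of Gene Family Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the birth-and-death history of a gene
    family across a species phylogeny. Provides species-overlap labelling of
    gene-tree duplication nodes and extraction of ortholog clades, Dollo
    parsimony and LCA reconciliation to place gene origins, duplications and
    losses on a species tree, inference of ancestral gene orders from
    conserved adjacencies, scanning of upstream regions for regulatory
    motifs with position weight matrix comparison, and statistical calling
    of receptor responses from luminescence assay plates (area under the
    curve, one-sided t-tests with Benjamini-Hochberg false discovery rate
    control, and Fisher exact enrichment). Includes seeded simulators for
    gene gain and loss, planted upstream motifs and assay plates, plus a
    curated fixture encoding the vertebrate taste-receptor (TAS1R) family
    repertoire used throughout the documentation and tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
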