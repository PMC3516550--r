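Package: tiescore
Title: Cross-Loci Integration of QTL, Expression, and Protein Interaction
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the joint regulation of a quantitative
    trait by two genetic loci in an F2 intercross. Implements single-marker
    LOD scans with permutation genome-wide thresholds, transcriptome-wide
    eQTL mapping with cis/trans classification and trait-QTL overlap, a
    likelihood-based causal/reactive/independent test for locus-gene-trait
    triplets, construction of the cross-locus protein-protein interaction
    network, and the Trait-Interaction-Expression (TIE) ranking of candidate
    regulator genes with permutation p-values. Includes a synthetic F2 cross
    generator with a planted regulatory hub for end-to-end validation, plus
    a generic hypergeometric gene-set enrichment test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
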