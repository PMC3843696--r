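Package: emmernet
Title: Reticulate Ancestry Analysis for Predominantly Selfing Plants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting and quantifying reticulate (network-like)
    ancestry in predominantly self-pollinating plants such as emmer wheat.
    Encodes sequence alignments and binary insertion-marker tables as
    phylogenetic splits, builds median-joining haplotype networks and
    filtered supernetworks (Z-closure with minSupportingTrees filtering),
    runs maximum-parsimony searches with bootstrap and consensus to compute
    concatenated-versus-per-locus incongruence ratios, counts minimum
    hybridization events between rooted gene-tree pairs via exact
    agreement-forest search, and simulates the loss of founder genotypes in
    mixed stands under rare outcrossing. Includes a synthetic-data generator
    with planted hybridization events so every stage of the pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
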