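Package: cernet
Title: Competing Endogenous RNA Network Inference for circRNA-miRNA-mRNA Axes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers circRNA-associated competing endogenous RNA (ceRNA) networks
    from bulk expression data of case/control designs, as used in ovariectomized
    (OVX) mouse models of postmenopausal osteoporosis. Implements differential
    expression at fold-change/p-value thresholds (median-of-ratios normalization
    and Welch t-tests), sequence-level miRNA response element (MRE) prediction
    with seed matching, a miRanda-style weighted local duplex alignment and an
    additive pair-energy model, signed Pearson coexpression filtering,
    hypergeometric shared-miRNA ceRNA scoring, direction-consistent network
    assembly with SIF/GraphML export, gene-set over-representation analysis, and
    2^-ddCt qPCR relative quantification. Ships a fully self-consistent
    synthetic-data generator with planted ceRNA circuits so that every stage can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    DESeq2,
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
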