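Package: aphidsex
Title: Sexually Antagonistic Selection and X-Linked Expression Bias Under
    Cyclical Parthenogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and simulates the invasion of sexually antagonistic
    mutations on the X chromosome versus autosomes under an aphid-like life
    cycle (many clonal generations followed by one sexual generation, with
    X0 males produced by parthenogenetic X loss), including closed-form
    invasion growth rates, stochastic genotype-count simulations, parameter
    sweeps with invasion classification, and a standard XX/XY control model.
    Also provides a morph-stratified RNA-seq analysis toolchain: a synthetic
    count-matrix generator with planted sex-biased genes, median-of-ratios
    normalization, a negative-binomial likelihood-ratio test for morph
    effects, fold-change bias-category classification, marker-window
    assignment of genes to the X or autosomes, chi-square enrichment
    statistics, and dosage-compensation comparisons on RPKM.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    GenomicRanges,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
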