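Package: cavenet
Title: Cooccurrence Networks and Keystone Taxa for Microbiome Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for the statistical analysis of
    amplicon count tables from environmental microbiomes, built around the
    workflow used in cave and subsurface methanotroph studies: rarefaction and
    prevalence filtering of OTU/ASV tables, alpha diversity (Chao1, Shannon)
    with Kruskal-Wallis group tests, Bray-Curtis beta diversity with PCoA and
    UPGMA clustering, Mantel permutation tests against environmental
    gradients, signed cooccurrence networks from Spearman correlations with
    Benjamini-Hochberg control, network topology summaries, Louvain module
    detection, and Zi-Pi (within-module connectivity / participation
    coefficient) node-role classification with keystone-taxon extraction.
    Includes a seeded synthetic community generator with planted modules,
    connectors, and environmental gradients so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
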