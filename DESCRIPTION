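Package: eggbiome
Title: Phylogeny-Aware Analysis of Egg-Associated Bacterial Communities
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing 16S rRNA amplicon surveys of bacterial
    communities on naturally spawned fish eggs across river networks:
    read-level quality filtering and negative-control decontamination,
    alpha diversity (Chao 1, observed species, Faith's phylogenetic
    diversity) with rarefaction, unweighted and weighted UniFrac
    distances, principal coordinates analysis, permutational community
    comparisons (PERMANOVA, ANOSIM, dispersion homogeneity), a
    read-resampling bootstrap test comparing one community against a
    group, Mantel and partial Mantel isolation-by-distance analyses with
    flow-corrected river distances, Jost's D population differentiation
    from microsatellite genotypes, temperature-diversity association
    (Kendall rank correlation, incubation-period means, forward stepwise
    regression), and a synthetic study generator that emulates the full
    sampling design so every stage can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    withr
Config/testthat/edition: 3
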