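Package: biomepair
Title: Paired Tumor and Non-Tumor Tissue Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired tumor/non-tumor two-kingdom
    (bacteriome and mycobiome) amplicon count data. Provides abundance-table
    input/output and manipulation (rank aggregation, relative abundance,
    read-depth pair filtering), community diversity and dissimilarity metrics
    (Shannon index, richness, Bray-Curtis, unweighted UniFrac, principal
    coordinates analysis, UPGMA dendrograms), per-taxon Kruskal-Wallis
    screening with Bonferroni-Dunn post-hoc adjustment, intra- and
    inter-kingdom rank-correlation screens, and a random-forest layer with
    out-of-bag vote fractions, permutation-importance nulls, backward
    variable elimination, 0.632+ bootstrap error estimation, and a paired
    vote-fraction-difference statistic for detecting field-cancerization
    effects. A Dirichlet-multinomial cohort simulator with planted
    compositional effects makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    randomForest,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
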