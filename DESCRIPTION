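Package: cryonet
Title: Niche Breadth, Gene Co-Occurrence Networks and Meteorological
    Drivers of Glacier Cryoconite Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-annotation analysis of cryoconite metagenome abundance
    tables. Classifies species-level genome bins into niche-breadth groups
    (Levins' index against a fixed-margin permutation null), contrasts
    genome features and gene redundancy across groups, builds a weighted
    KEGG-ortholog co-occurrence network (CLR-transformed abundances,
    soft-thresholded adjacency, topological overlap, tree-cut modules,
    eigengenes), selects radiation-predictive modules by L1-regularized
    regression, extracts biofilm-associated hub genes, and attributes
    community variation to meteorological covariates by redundancy
    analysis, hierarchical partitioning and multiple regression on
    distance matrices. Ships a synthetic-data generator emulating the
    statistical structure of hemispheric cryoconite surveys so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    geosphere,
    igraph,
    stats,
    utils,
    vegan
Suggests:
    glmnet,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
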