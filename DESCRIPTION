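Package: rarefungi
Title: Biotic Homogenization and Rare-Taxon Analysis for Soil Fungal Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for detecting biotic homogenization of
    soil fungal communities across land-use types. Reads and validates
    OTU-by-site count tables, rarefies to a fixed depth, and computes alpha
    diversity (richness, Shannon, ACE) with nonparametric group tests;
    Bray-Curtis dissimilarity, principal coordinate analysis, sequential-SS
    PERMANOVA, and simple/partial Mantel tests against geographic and
    environmental distances; square-root rank cumulative abundance curves with
    per-rank Welch tests; Levins' niche breadth with a depth-aware multinomial
    permutation null and an occupancy-plus-niche-breadth rarity classifier;
    polynomial latitude/longitude models selected by AICc, covariate PCA with
    collinearity pruning, and a PCA-based agricultural management-intensity
    index. Includes a synthetic community generator with a controllable
    homogenization effect so every stage can be verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
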