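Package: microassembly
Title: Null-Model Analysis of Microbial Community Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multi-phasic null-model toolkit for quantifying the ecological
    processes that assemble microbial communities from amplicon sequence
    variant (ASV) tables and a rooted phylogeny. Implements the nearest taxon
    index (NTI) environmental-filtering screen with a richness null, pairwise
    beta-nearest-taxon statistics (betaMNTD, betaNTI) with a tip-shuffling
    null, abundance-based Raup-Crick with Bray-Curtis (RC-bray) and the
    five-way quantitative process estimate (QPE) classification into variable
    selection, homogeneous selection, dispersal limitation, homogenizing
    dispersal and undominated turnover, the normalised stochasticity ratio
    (NST) under Jaccard and Ruzicka metrics with proportional-proportional and
    proportional-fixed richness constraints plus a permutational significance
    test, and a competitive lottery model for clade-level winner detection.
    Ships a synthetic-community generator that simulates phylogenies, Brownian
    traits and ASV tables under known assembly regimes so every inference
    stage can be validated against ground truth, and a one-call pipeline that
    orchestrates the full analysis reproducibly from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    vegan,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
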