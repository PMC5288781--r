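Package: seadrift
Title: Larval Dispersal Connectivity, Oceanographic Clustering and
    Coalescent Species Delimitation for Island Archipelagos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying archipelagic endemism in marine invertebrates
    with pelagic larvae. Generates synthetic seascapes (coastal cell grids with
    rock/sand substrate and divergence-free, time-varying surface current
    fields), releases and advects passive Lagrangian particles to record
    effective shore-to-shore dispersal, aggregates dispersal events into
    directed island connectivity probability matrices, clusters the resulting
    weighted island network by percolation-threshold pruning and
    leading-eigenvector community detection with a permutation test on
    modularity, fits the single-threshold general mixed Yule-coalescent (GMYC)
    model for species delimitation on ultrametric trees with a likelihood
    ratio test, and provides small biogeographic statistics (nested-model
    likelihood ratio comparison, richness-substrate correlation). Ships the
    published 4-day and 30-day island connectivity matrices for the Cape Verde
    keyhole limpet system as fixtures.
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
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
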