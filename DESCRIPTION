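Package: ecoassembly
Title: Community Assembly Inference for Microbial Ecology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for inferring the ecological processes
    that assemble microbial communities from a sample-by-taxon abundance table,
    a rooted phylogeny, and sample metadata. Implements beta mean nearest taxon
    distance (betaMNTD) and the beta nearest taxon index (betaNTI) under a
    taxa-shuffle null, Bray-Curtis-based Raup-Crick (RCbray) under a
    probabilistic assembly null, the five-process classification of community
    assembly (homogeneous and variable selection, homogenizing dispersal,
    dispersal limitation, drift), the Sloan neutral community model fit,
    the phylogenetic normalized stochasticity ratio (pNST), beta-diversity
    partitioning into replacement and richness-difference components, UPGMA
    clustering, distance-based redundancy analysis, distance-decay regression,
    and FDR-filtered co-occurrence networks with Zi-Pi keystone-taxon calling.
    A synthetic-community generator with known assembly regimes (neutral,
    selection, dispersal limitation) provides ground-truth recovery tests for
    every inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    picante,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
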