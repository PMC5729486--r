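Package: necknet
Title: Anatomical Network Analysis of Mammalian Neck Musculoskeletal
    Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the musculoskeletal system of the mammalian neck as an
    undirected anatomical network (bones, muscles and ligaments as nodes,
    physical contacts and attachments as links) and analyses its topology in
    an evolutionary context. Computes the seven standard anatomical-network
    descriptors (node and link counts, density, clustering, path length,
    degree heterogeneity and parcellation), detects connectivity modules by
    simulated annealing of Newman-Girvan modularity with jackknife errors and
    per-module rank-sum significance, and runs phylogenetic comparative
    analyses on the species-by-parameter matrix: Blomberg's K and its
    multivariate extension, Abouheif's Cmean, Brownian-motion /
    Ornstein-Uhlenbeck / early-burst model comparison by AIC weights,
    phylogenetic generalized least squares, distance-based PGLS with residual
    permutation, coefficient-of-variation equality tests, and disparity
    through time with a Brownian-motion null. A synthetic-data module
    generates neck-like networks, calibrated trees and simulated traits so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
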