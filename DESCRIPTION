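Package: mimicry
Title: Spatial and Phylogenetic Analysis of Batesian Mimicry Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether noxious model species predict the
    geography and evolutionary history of their Batesian mimics, built around
    the New World coral-snake / red-black-banded (RBB) colubrid system.
    Constructs species ranges from occurrence records (alpha hulls, convex
    hulls, point buffers), rasterizes richness and abundance on latitude/
    longitude grids, and tests model-mimic co-occurrence with spatial
    autoregressive error models and a structure-preserving permutation null.
    Fits two-state Markov (Mk) models of colour-pattern evolution with
    clade-specific rate partitions found by stepwise AIC, samples Bayesian
    posterior rates by MCMC, and draws stochastic character maps to summarize
    gains and losses of the mimetic phenotype through time and latitude,
    including Brownian-motion ancestral latitude reconstruction and a
    contrasts-based test of latitudinal conservatism. A synthetic-data module
    generates trees, trait histories, latitudes and virtual-continent
    biogeography with known parameters so every stage can be validated
    against ground truth.
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
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    geosphere,
    Matrix,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
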