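Package: ryrscape
Title: Spatial Statistics, Reconstruction and Calcium Dynamics of RyR Cluster Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterising and simulating the spatial organisation of
    ryanodine-receptor (RyR) clusters in cardiomyocytes and its consequences for
    the rising intracellular calcium transient. Implements the four classical
    point-pattern summary functions (F, G, K, pair correlation) with Monte-Carlo
    envelope hypothesis testing, an energy-minimisation reconstruction algorithm
    that places clusters on voxelised myofibril/mitochondria templates, a
    synthetic template and pattern generator, a finite-volume reaction-diffusion
    solver for calcium with dye and buffer kinetics on the voxel grid, and
    confocal line-scan image synthesis (PSF convolution, downsampling, Poisson
    noise).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
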