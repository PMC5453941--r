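Package: porescape
Title: Trajectory Analysis of Protein Cargo Permeation Through Membrane Pores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for coarse-grained and all-atom simulation
    trajectories of protein cargo permeating oligomeric membrane pores.
    Computes two-dimensional free-energy landscapes by Boltzmann inversion
    of positional histograms, stage-wise one-dimensional potentials of mean
    force with basin and barrier extraction, residue-residue contact maps
    and polarity-classified contact fractions, lipid bilayer density
    profiles and second-rank chain order parameters, pore-shape
    (ellipticity) and cavity-size metrics, Shrake-Rupley solvent-accessible
    surface areas with four-class polarity decomposition, and rigid-body
    fragment back-mapping of coarse-grained helices to all-atom
    coordinates.  Includes seeded synthetic-trajectory generators
    (Metropolis Monte Carlo with replica exchange, bilayer, pore-ring,
    cargo-placement and ion generators) with known statistical ground
    truth, so every analysis stage admits parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
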