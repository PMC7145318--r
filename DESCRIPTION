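Package: sugartraj
Title: Trajectory Analysis of Sugar-Water Mixtures: Hydrogen Bonding,
    Clustering, Transport and Glass Transition
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of
    trehalose-water mixtures under periodic boundary conditions: geometric
    hydrogen-bond detection and census, reactive-flux hydrogen-bond kinetics,
    site-site radial distribution functions with running integrals, spatial
    and combined (distance-angle) distribution functions, dihedral
    distributions, cluster identification with periodic-image percolation
    detection, Einstein-relation self-diffusion with Arrhenius diagnostics,
    glass-transition extraction from density-temperature curves with
    Couchman-Karasz comparison, and pairwise Lennard-Jones plus Coulomb
    interaction-energy decomposition. Ships synthetic-trajectory generators
    with known ground truth (rigid pseudo-disaccharide templates, Brownian
    dynamics, two-state telegraph bond kinetics, clustered and percolating
    configurations, density curves) so every analysis stage is testable
    without an MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
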