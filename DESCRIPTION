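Package: mempore
Title: Trajectory Analysis of Peptide Pore Formation on Lipid Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analyses molecular trajectories of membrane-bound peptide
    aggregation and ion-channel formation: centre-of-mass clustering under
    periodic boundary conditions, radius of gyration and Shrake-Rupley
    solvent-accessible surface area, two-dimensional free-energy landscapes
    by Boltzmann inversion with basin detection and minimax saddle barriers,
    nematic order parameters of peptide bundles, axial density profiles with
    density-based potentials of mean force, pore-radius estimation from the
    projected lumen area, and water/ion permeation-event counting.  A
    synthetic-trajectory generator reproduces the statistical structure the
    analyses assume, so every estimator is testable against a known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
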