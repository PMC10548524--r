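Package: oxykin
Title: Trajectory Statistics and Kinetics of Gas Handling in Protein Cavities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for gas-migration statistics in molecular
    dynamics trajectories of cofactor-independent dioxygenases: 3D occupancy
    density mapping and pocket (site) detection, Boltzmann inversion and
    bias reweighting of occupancy probabilities with minimax (bottleneck)
    barrier estimation, censored residence-time survival statistics with
    exponential maximum-likelihood and cumulative-event estimation of escape
    rates, side-chain chi1 rotamer classification and occupancy-conditioned
    distributions, iterative superposition with per-atom RMSF, active-site
    geometry descriptors (signed dihedrals, ring-plane distances, contact
    shells), and nonadiabatic (spin-forbidden) barrier corrections for
    intersystem-crossing-limited reactions. Includes a seeded synthetic
    trajectory/event generator emulating the statistical structure of gas
    hopping, escape and rotamer switching, so every stage is testable
    without MD engines.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
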