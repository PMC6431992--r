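Package: poretrans
Title: Dynamic Monte Carlo Simulation of Semiflexible Polymer Translocation
    into a Slab Between Two Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Off-lattice dynamic Monte Carlo simulator for a charged
    semiflexible bead-spring polymer driven by an electric field through a
    nanopore into the laterally unbounded space between two parallel
    repulsive membranes. The chain is modelled with FENE bonds, Morse
    excluded-volume interactions, a harmonic-in-cosine bending potential and
    short-ranged Morse wall repulsion. The package provides the Metropolis
    translocation protocol (cis-side equilibration, release, withdrawal
    restarts), ensemble drivers, observables (translocation times, per-monomer
    waiting-time profiles, time distributions, post-translocation
    projections), parameter sweeps and log-log power-law scaling fits, plus
    CSV/XYZ/JSON input-output for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
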