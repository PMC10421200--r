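Package: nanosorb
Title: Adsorption Free Energies at Nanomaterial Surfaces by Metadynamics
    with Mean-Force Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for estimating biomolecule adsorption free
    energies at inorganic nanosurfaces, built around zinc-blende ZnS.
    Constructs crystals, (110) slabs and spherical nanoparticles with
    coordination-based pruning and bond/angle topology; fits harmonic
    bonded parameters to Buckingham-plus-Coulomb pair potentials and
    evaluates the resulting bonded force field; runs energy minimisation
    and Langevin/NVT molecular dynamics with an optional metadynamics bias
    on the surface-separation-distance collective variable; recovers
    potentials of mean force by integration of the unbiased mean force and
    by Boltzmann inversion; computes layer-averaged adsorption free
    energies with standard-state corrections, binding-mode classification
    and block-averaged errors; and analyses interfacial structure (density
    profiles, water orientation distributions, radial distribution
    functions). Synthetic generators with analytically known answers make
    every estimator testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
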