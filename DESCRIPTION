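Package: cgnp
Title: Coarse-Grained Modelling of Monolayer-Protected Gold Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Build, simulate and analyse coarse-grained models of
    self-assembled-monolayer gold nanoparticles. The package constructs
    rigid Au/CD core topologies with octanethiol (OT) and
    mercaptoundecanoic-acid (MUA) ligand shells, houses a SPICA-style
    force field (harmonic bonded terms, Lennard-Jones 9-6 and 12-4
    nonbonded forms) with the core-decoy (CD) bead pair table and its
    substitution rules, and provides a desk-scale molecular dynamics
    engine with rigid-body cores, Langevin thermostatting and
    centre-of-mass restraints. On top of the engine it implements the
    relative-entropy grid-search pipeline used to derive CD nonbonded
    parameters from radial distribution functions, umbrella-sampling
    window generation with WHAM reconstruction of dimerization free
    energy profiles, and aggregation observables (nanoparticle
    radial distribution functions, cluster detection, aggregation
    kinetics with saturating-exponential fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    igraph,
    minpack.lm,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
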