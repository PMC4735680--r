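Package: ilbilayer
Title: Coarse-Grained Modelling of Ionic-Liquid Insertion into Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how imidazolium-based ionic-liquid cations
    partition into and soften phospholipid bilayers at coarse-grained
    resolution. Provides an SDK-style Mie (9-6 / 12-4) plus screened-Coulomb
    energy model with analytic forces, a desk-scale Langevin/semi-isotropic
    NPT integrator, WHAM reconstruction of cation-insertion free-energy
    profiles with PMF-matching refinement of cation-lipid cross interactions,
    and Helfrich fluctuation-spectrum analysis of leaflet undulations
    yielding bending moduli and inserted-cations-per-lipid statistics.
    Synthetic-data generators (exact Helfrich surface sampler, umbrella-window
    Metropolis sampler, toy bilayer builder) supply ground-truthed inputs for
    every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
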