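Package: edlmc
Title: Primitive-Model Monte Carlo for Spherical Electric Double Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Canonical Metropolis Monte Carlo simulation of the spherical
    cell model of a charged colloid: a hard-sphere macroion fixed at the
    centre of a spherical cell, neutralised by explicit hard-sphere
    counterions and, optionally, multivalent salt in a dielectric continuum
    solvent. Computes radial distribution functions, the accumulated
    running charge, mean electrostatic potential, surface and zeta
    potentials, effective macroion charge, and reduced electrostatic
    energy, and sweeps these observables over solvent dielectric constant,
    salt content and salt valence to study charge inversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
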