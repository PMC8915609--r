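Package: ljrefit
Title: Lennard-Jones Parameter Refitting Against Solvation Free Energies
    and Liquid Densities
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for optimizing Lennard-Jones self- and
    water-interaction parameters of a fixed-charge force field against
    experimental solvation free energies and liquid densities. Provides a
    parameter data model with modified Lorentz-Berthelot combining rules,
    implicitly polarized charge construction and mixture charge
    interpolation, a Metropolis Monte Carlo engine for periodic
    Lennard-Jones/point-charge fluids, alchemical solvation free energy
    estimation via a 1-1-48 softcore pathway and the multistate Bennett
    acceptance ratio (MBAR) with bootstrap errors and lambda-schedule
    redistribution, a weighted RMSD-ratio objective with Nelder-Mead
    simplex search and a sequential atom-type adaptation scheduler,
    relative solubility prediction, and a seeded synthetic-data generator
    so the entire fit-evaluate loop is testable without external molecular
    dynamics or quantum chemistry software.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
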