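Package: wpesim
Title: Hybrid Monte Carlo-Molecular Dynamics Simulation of Weak
    Polyelectrolyte Titration with Explicit Salt
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained constant-pH simulation of weak polyacid chains
    and stars in explicit mono- and divalent salt.  Couples
    reaction-ensemble Monte Carlo (de)protonation against a hydroxide
    chemostat, grand-canonical exchange of charge-neutral salt and base
    units, and charge-annealing swap moves to Langevin molecular-dynamics
    relaxation of a bead-spring model with truncated-shifted
    Lennard-Jones adhesion, FENE bonds and Ewald-summed Coulomb
    electrostatics.  Includes reservoir calibration of chemical
    potentials against bulk concentrations, Debye-length conversion,
    titration and conformational observables (charge fraction, radius of
    gyration, ion shell histograms) with block statistics, and
    deterministic fixture generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tibble,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
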