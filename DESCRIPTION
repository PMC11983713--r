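Package: aquann
Title: Neural-Network Polarizable Three-Site Water Model with Charge Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A flexible three-site water force field in which atomic partial
    charges and intermolecular charge transfer are predicted on the fly by
    small dense neural networks from interaction-classified radial descriptors
    of each atom's local environment. Provides analytic energy gradients
    (including the chain rule through the networks and the charge
    neutralization shift), Ewald electrostatics for orthorhombic cells, a
    velocity-Verlet molecular dynamics engine with a Langevin thermostat, a
    fixed-charge flexible SPC/FW baseline, gas-phase dimer optimization,
    liquid and droplet analysis observables (radial distribution functions,
    infrared spectra from dipole autocorrelation, self-diffusion, tetrahedral
    order, shell charge densities), and a synthetic surrogate-label generator
    so the full train/predict/simulate loop is exercisable without
    quantum-chemistry reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
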