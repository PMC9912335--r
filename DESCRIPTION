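Package: neotrap
Title: Simulation and Analysis of Nanopore Electro-Osmotic Trap Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the nanopore electro-osmotic trap (NEOtrap), a solid-state
    nanopore with a docked porous DNA-origami sphere that traps single unmodified
    proteins by electro-osmotic flow. Provides an axisymmetric finite-volume
    Poisson-Nernst-Planck-Stokes-Brinkman solver for the docked-sphere geometry
    (vertical versus horizontal origami orientation, anisotropic nanochannel
    permeability), a synthetic current-trace generator (telegraph-state kinetics,
    Gaussian white plus 1/f noise, Bessel low-pass filtering, voltage protocols),
    event detection with dwell-time maximum-likelihood and bootstrap rate
    estimation, noise spectral metrics, and conversion of kinetic contrasts into
    trapping-barrier and drag-force estimates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
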