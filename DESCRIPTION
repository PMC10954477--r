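Package: rdflux
Title: Relaxation Dispersion Fitting and Misincorporation Flux Modeling
    for Transient Watson-Crick-Like Mismatches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and global fitting of off-resonance 15N R1rho
    relaxation dispersion profiles to two- and three-state Bloch-McConnell
    chemical exchange models, as used to characterize transient tautomeric and
    anionic Watson-Crick-like G.T/U mismatches in nucleic-acid duplexes.
    Includes Henderson-Hasselbalch pKa determination from chemical-shift
    titrations and from excited-state populations, pH-dependent extrapolation
    of exchange kinetics, and an equilibrium kinetic-flux model partitioning
    misincorporation errors between the tautomeric and anionic pathways.
    Synthetic-data generators reproduce the acquisition grid and noise
    characteristics of 1D selective-excitation R1rho experiments.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
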