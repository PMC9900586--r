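Package: radicalpair
Title: Radical-Pair Spin Dynamics for Magnetic Compass Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the coherent spin dynamics of flavin-based radical
    pairs (FAD-Trp and FAD-Z) in an Earth-strength magnetic field and
    computes the direction-dependent singlet reaction yield and its
    anisotropy, the quantity thought to underlie the magnetic compass of
    migratory birds. Supports arbitrary 1H/2H, 12C/13C and 14N/15N isotope
    substitutions via magnetogyric-ratio scaling and tensor insertion,
    combinatorial screening of carbon isotopologues, and libration-induced
    spin relaxation through a two-site stochastic Liouville model. Ships a
    synthetic flavin-like hyperfine tensor generator so every stage is
    testable without external quantum-chemistry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
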