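Package: alchemfep
Title: Indirect Alchemical Free-Energy Toolkit for Host-Guest Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for indirect (reference-potential) binding free-energy
    calculations on small molecular systems. Provides CHARMM-functional-form
    energies and analytic forces with alchemical soft-core decoupling and a
    flat-bottom centre-of-mass restraint, Boltzmann sampling of toy systems
    by Metropolis Monte Carlo, force-matched refitting of bonded parameters
    against target-level forces, free-energy estimators (Zwanzig/FEP, BAR,
    MBAR) with block-averaged uncertainties, double-decoupling and
    protonation-state thermodynamic-cycle bookkeeping with restraint and
    standard-state corrections, Lambert-W-based one-sided convergence
    diagnostics, and blind-challenge accuracy statistics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
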