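Package: nocicoox
Title: Nonorthogonal Configuration Interaction over Constraint-Based
    Orbital-Optimized Excited States
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Excited-state electronic structure by nonorthogonal
    configuration interaction (NOCI) over constraint-based
    orbital-optimized reference determinants (COOX).  Implements
    constrained self-consistent field theory with a density-constraint
    Lagrange multiplier, automatic excitation-space selection by orbital
    energy windows, pairwise biorthogonal (generalized Slater-Condon)
    overlap and Hamiltonian matrix elements via singular value
    decomposition, a transition-density-functional correction for
    Kohn-Sham references, spin expectation values and spin purification,
    transition densities, oscillator strengths and Voigt-broadened
    spectra.  Ships a self-contained McMurchie-Davidson Gaussian integral
    engine, SVWN5/PBE-family exchange-correlation functionals on Becke
    molecular quadrature grids, a Tamm-Dancoff excitation solver, an
    initial-maximum-overlap-method (IMOM) driver for comparison states,
    and brute-force permutation-expansion oracles for validation on
    few-electron systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
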