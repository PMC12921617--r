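Package: fieldcycle
Title: Magnetic Field Cycling NMR Analysis: Shimming, Relaxometry, and
    Hyperpolarization Budgets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for magnetic field cycling (MFC) NMR of
    hyperpolarized tracers. Provides regularized least-squares shimming of a
    mu-metal shield (nine shim coils, analytic gradients, Hessian-based
    confidence intervals, iterative fine tuning), field calibration lookup
    tables and shuttle kinematics, nuclear magnetic relaxation dispersion
    (NMRD) model fitting for [1-13C]pyruvate with globally fitted
    biexponential decays, polarization-loss integrals over transfer field
    profiles, SABRE-SHEATH chemical-exchange kinetics, and seeded synthetic
    generators for every input kind.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
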