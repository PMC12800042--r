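Package: fracCRC
Title: Fractional-Order Colon Cancer Dynamics Under Combination Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and stability analysis of a Caputo fractional-order
    model of colon cancer under combined chemotherapy, immunotherapy and
    probiotic dosing. The model couples tumor cells, macrophages, dendritic
    cells, CD4+ T helper cells and a probiotic drug concentration through
    saturating (Michaelis-Menten-type) interactions. The package provides the
    model right-hand side (base and extended variants), a full-memory
    Adams-Bashforth-Moulton predictor-corrector (PECE) integrator for Caputo
    systems with a Mittag-Leffler evaluator and an integer-order reference
    solver as oracles, closed-form and root-finding computation of tumor-free
    and coexistence equilibria, linearized stability classification via
    Routh-Hurwitz determinants and the Matignon criterion, Lipschitz/Picard
    well-posedness diagnostics, and a registry of ready-to-run therapy
    scenarios with parameter sweeps and summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
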