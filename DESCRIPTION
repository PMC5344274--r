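Package: emtdorm
Title: Deterministic and Stochastic Models of EMT-Driven Tumor Dormancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Population-dynamic models of dormant micrometastatic tumors
    composed of mesenchymal (stem-like) and epithelial (differentiated)
    cells coupled by epithelial-mesenchymal transition (EMT). Provides a
    two-compartment ordinary differential equation engine (linear and
    saturated epithelial feedback, with and without EMT) with analytic
    steady states, Jacobian-based stability classification, the
    transcritical-bifurcation threshold of the epithelial death rate,
    local finite-difference sensitivity analysis, death-rate parameter
    sweeps and piecewise chemotherapy treatment schedules; and a
    generation-synchronous branching simulator of asymmetric stem
    division with finite epithelial generational capacity and
    per-division EMT events, including batch experiments for EMT
    occurrence and post-treatment tumor recurrence with exact analytic
    oracles. A command-line interface exposes both engines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
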