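Package: gutpk
Title: Kinetic Models of Gut-Secreted Heat-Shock Proteins and Glucose-Insulin Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation tools for the serum kinetics of
    gut-secreted chaperones (HSP70, GRP78) with Michaelis-Menten
    receptor-mediated clearance, quasi-steady-state target-mediated
    disposition of their blocking monoclonal antibodies, the oral glucose
    minimal model of insulin sensitivity, two-compartment C-peptide
    deconvolution of insulin secretion with beta-cell responsivity, the
    disposition-index hyperbola, and a linear model linking fasting serum
    chaperone levels to the NAFLD Activity Score. Includes synthetic-data
    generators with known ground truth so every estimator can be validated
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
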