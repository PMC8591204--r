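Package: ecmopk
Title: Population Pharmacokinetics and Dosing Simulation of Meropenem
    During Extracorporeal Membrane Oxygenation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-compartment population pharmacokinetic modelling of
    meropenem in critically ill adults receiving extracorporeal membrane
    oxygenation (ECMO). Provides exact closed-form kinetics for zero-order
    intravenous infusions, a covariate model linking creatinine clearance
    to total clearance and ECMO blood-flow rate to central volume,
    first-order conditional estimation with interaction (FOCE-I) of the
    nonlinear mixed-effects model, stepwise covariate selection,
    nonparametric bootstrap, residual and visual-predictive-check
    diagnostics, a synthetic-cohort generator emulating the study design,
    and Monte Carlo simulation of the probability of pharmacodynamic
    target attainment (fT>MIC) across dosing regimens, renal-function
    groups and ECMO flow rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
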