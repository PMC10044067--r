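Package: cippk
Title: Population Pharmacokinetics and Target Attainment for Piperacillin
    Continuous Infusion
Version: 0.1.0
Authors@R: person("Analytics", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of beta-lactam
    antibiotics given by continuous infusion to critically ill patients with
    preserved renal function. Provides a two-compartment disposition model
    with zero-order infusion input (closed-form and ODE solutions, including
    Michaelis-Menten elimination variants), renal-function equations
    (CKD-EPI, Cockcroft-Gault, MDRD-4), a first-order conditional estimation
    with interaction (FOCEI) nonlinear mixed-effects engine with stepwise
    covariate selection and standard diagnostics (CWRES, shrinkage,
    non-parametric bootstrap, prediction-corrected visual predictive
    checks), a synthetic critically-ill cohort generator for sparse
    two-window sampling designs, and Monte Carlo simulation of probability
    of target attainment (PTA) and cumulative fraction of response (CFR)
    across dosing regimens, renal-function strata and MIC distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
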