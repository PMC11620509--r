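Package: pedmero
Title: Population Pharmacokinetics of Meropenem in Critically Ill Children
    With and Without Continuous Kidney Replacement Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated population pharmacokinetic modelling of meropenem in
    critically ill children, including patients on continuous kidney
    replacement therapy (CKRT). Provides a two-compartment multi-matrix
    structural model (plasma/prefilter, postfilter, effluent, urine) with
    partitioned renal, metabolic and extracorporeal clearances, a covariate
    model with age maturation and eGFR scaling of renal clearance, synthetic
    cohort generation emulating a sparse paediatric sampling design,
    nonlinear mixed-effects estimation by Laplace approximation with
    stepwise covariate modelling, simulation-based diagnostics
    (prediction-corrected visual predictive checks, sampling importance
    resampling), and Monte-Carlo probability-of-target-attainment dosing
    simulations with toxicity bounds.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
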