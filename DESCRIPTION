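Package: vedopk
Title: Population Pharmacokinetics of Vedolizumab for GvHD Prophylaxis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects population pharmacokinetic modelling of
    intravenous vedolizumab given for acute graft-versus-host disease
    prophylaxis in adults undergoing allogeneic haematopoietic stem cell
    transplantation. Implements a two-compartment linear infusion model with
    allometric and power-law covariate submodels, inter-individual and
    inter-occasion log-normal random effects, and first-order conditional
    estimation with interaction (FOCE-I). Includes a synthetic trial
    generator emulating a phase 1b rich-sampling study and a phase 3
    trough-sampling study, NONMEM-dialect event-record input/output with
    below-quantification-limit exclusion, simulation-based diagnostics
    (prediction-corrected visual predictive checks, normalized prediction
    distribution errors), and covariate forest-plot inference on relative
    clearance under parameter uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
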