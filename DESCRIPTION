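Package: tacropk
Title: Population Pharmacokinetics and Initial Dose Optimization of
    Tacrolimus in Pediatric SCID-HSCT Patients
Version: 0.1.0
Authors@R: person("tacropk", "maintainers", email = "tacropk@example.org",
    role = c("aut", "cre"))
Description: Population-pharmacokinetic workflow for twice-daily oral
    tacrolimus in young children after hematopoietic stem cell
    transplantation for severe combined immunodeficiency: one-compartment
    first-order absorption kinetics with allometric body-weight scaling, a
    synthetic trough-sampling cohort generator, nonlinear mixed-effects
    estimation (Laplace approximation with interaction) with stepwise
    covariate selection, nonparametric bootstrap validation, goodness-of-fit
    diagnostics, and Monte Carlo probability-of-target-attainment tables for
    initial-dose recommendation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
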