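Package: csmigrate
Title: Compartment Modelling of Long-Term Caesium-137 Vertical Migration
    in Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the slow vertical migration of fallout
    caesium-137 through layered soil: fractional layer contributions from
    soil-profile activity tables, radioactive-decay backdating and areal
    deposition arithmetic, closed-form solutions of a six-compartment
    catenary transfer chain with equal or distinct transfer rates, a
    fixed-step Runge-Kutta oracle for verification, single-parameter
    least-squares estimation of the transfer rate with asymptotic and
    bootstrap uncertainty, comparison of equal-rate versus increasing-rate
    chains, and a synthetic-data generator reproducing the statistical
    design of a multi-decade sampling campaign.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
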