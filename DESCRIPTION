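Package: tfmodes
Title: Thermodynamic and Kinetic Models of Transcription Factor Regulatory Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a promoter regulated by a single transcription factor (TF)
    whose mechanism is split into two modes: stabilization of RNA polymerase at
    the promoter (beta) and acceleration of transcription initiation (alpha).
    Provides the closed-form equilibrium (thermodynamic) fold-change model, the
    full 4-state promoter chemical-master-equation model with protein birth and
    death (steady states, fold-change, noise moments, response times), exact
    stochastic simulation for simple regulation and autoregulation (monomer or
    dimer TF), mean-field analysis of autoregulated genes, noise-profile
    classification over TF concentration, and least-squares fitting of the two
    regulatory parameters to fold-change versus promoter-strength data with
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
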