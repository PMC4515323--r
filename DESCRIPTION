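Package: wdmnet
Title: Windowed Discrete Model Simulation of Multi-Valued Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multi-valued logical (discrete
    dynamical) networks with synchronous and asynchronous updating,
    exact and sampled attractor/basin-of-attraction analysis, and
    basin-weighted windowed averaging of node activities to emulate
    population-level expression measurements from batch cultures.
    Ships a 15-node model of the cAMP/PKA regulatory network of
    Saccharomyces cerevisiae together with a strain/condition library
    and a qualitative calibration suite for HSE-dependent gene
    expression under optimal temperature and heat shock.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
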