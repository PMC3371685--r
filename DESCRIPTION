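Package: melimm
Title: Delay Differential Equation Model of CTL and Anti-CD137
    Immunotherapy Against B16 Melanoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the competition between the immune system and B16-OVA
    melanoma under combined adoptive transfer of activated OT1 cytotoxic T
    lymphocytes and anti-CD137 (4-1BB) monoclonal antibodies. The model is a
    two-compartment system of seven nonlinear delay differential equations
    integrated by the method of steps with impulsive bolus injections. The
    package also maps cell counts to melanoma surface under a disk-shaped
    radial-growth assumption, fits Gompertz growth parameters to noisy
    surface measurements by nonlinear least squares, performs time-resolved
    global sensitivity analysis via Latin hypercube sampling and partial
    rank correlation coefficients with a dummy-parameter control, and
    generates synthetic per-mouse measurement cohorts so the whole pipeline
    runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
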