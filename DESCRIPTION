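Package: volecycles
Title: Agent-Based Simulation and Time-Series Analysis of Vole Population
    Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Spatially explicit, individual-based simulation of field vole
    (Microtus agrestis) populations under specialist and generalist
    predation in landscapes with varying habitat fragmentation, together
    with the time-series toolkit used to characterise the resulting
    dynamics: cycle amplitude, autocorrelation-based cycle-length
    detection with a white-noise confidence band, and second-order
    autoregressive estimates of direct and delayed density dependence.
    Includes a factorial experiment driver with ANOVA variance
    decomposition and synthetic time-series generators for validating the
    analysis stack independently of the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    tidyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
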