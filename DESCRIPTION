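Package: znbox
Title: Dynamic Box Models of Whole-Body Zinc Isotope Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental ("box") modelling of stable zinc isotope
    homeostasis in the mammalian body. Builds first-order kinetic networks of
    zinc pools with per-flux isotope fractionation, solves their steady-state
    delta-66-Zn compositions analytically, derives residence times and
    whole-system eigenvalue relaxation times, simulates diet-switch
    equilibration and periodic (seasonal) dietary forcing with buffering and
    phase-shift extraction, and re-fits poorly constrained fluxes and
    fractionation coefficients by sweeping parameter grids against observed
    confidence intervals. Ships the reference rat zinc cycle together with a
    synthetic-data generator for noisy tissue observation tables and
    diet-switch time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
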