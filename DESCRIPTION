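Package: fermh2
Title: Kinetic Modelling of Diauxic-Like Hydrogen Fermentation on Sugar
    Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates batch dark-fermentative hydrogen production by the
    extreme thermophile Caldicellulosiruptor saccharolyticus growing on
    glucose/xylose/arabinose mixtures.  The growth model combines Monod
    uptake kinetics, Hill-type induction of a second glucose uptake system
    under cybernetic control (reproducing diauxic-like two-phase sugar
    consumption), gas-liquid mass transfer of hydrogen and carbon dioxide,
    and fast carbonate acid-base speciation, integrated with a built-in
    stiff Rosenbrock solver.  Includes conversion-yield estimation from
    batch trajectories, lag-phase detection, one-factor-at-a-time local
    sensitivity analysis, non-linear least-squares parameter calibration
    with 95 percent confidence intervals, and a synthetic-data generator
    for the four canonical fermentation cases (single glucose, single
    xylose, defined sugar mixture, wheat straw hydrolysate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    yaml,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
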