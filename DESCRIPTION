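Package: presscontrol
Title: Moving-Horizon Estimation and Nonlinear MPC for a Rotary Tablet Press
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mechanistic simulation and quality-by-control of a rotary tablet
    press for continuous direct compression. Implements a Kawakita-based
    compaction model with glidant (colloidal silica) effects on bulk density
    and tensile strength, a noisy virtual plant with scheduled disturbances
    and plant-model mismatch, a moving-horizon estimator (MHE) that tracks
    uncertain model parameters and an output-disturbance median, a nonlinear
    model predictive controller (NMPC) with move blocking, and closed-loop
    orchestration with IAE, M2P and D2R control-performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
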