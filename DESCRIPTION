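Package: emboflow
Title: Reduced-Order Hemodynamic Modelling of Transcatheter Arterial
    Embolization Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for planning-oriented analysis of transcatheter arterial
    embolization (TAE) hemodynamics on reduced-order (0D) vascular networks.
    Generates seeded Murray's-law branching arterial trees, solves steady and
    quasi-steady pulsatile laminar flow as a Poiseuille resistance network
    with a prescribed inlet flow rate and per-outlet pressures, and computes
    the embolization efficiency index (EEI) -- the percentage of flow passing
    a candidate injection site that reaches designated target outlets -- at
    every segment of the tree.  Includes target-pressure and inlet-flow sweep
    pipelines, a flow-cessation (stall) pressure finder with an analytic
    cross-check, peripheral-resistance calibration to a requested stall
    pressure, retrograde-flow (backflow) detection under pulsatile inflow,
    tidy tibble outputs with broom-style tidy()/glance() methods, and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
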