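Package: evapsense
Title: Evaporation-Endpoint Microwave Resonator Modelling and Cell-Count Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models and calibration tools for evaporation-endpoint
    microwave resonator assays of white-blood-cell concentration. Provides
    equivalent-circuit design equations for printed LC resonators (spiral
    inductance, interdigital capacitance via complete elliptic integrals,
    resonant frequency), dielectric models (complex permittivity, penetration
    depth, the single-shell spherical cell model, Maxwell-Garnett effective
    medium mixing, frequency-regime classification), droplet and chip-surface
    geometry arithmetic, synthetic S11 sweep and evaporation time-course
    generation, Touchstone (.s1p) I/O, and linear concentration-frequency
    calibration with inverse prediction and uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
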