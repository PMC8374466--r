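Package: ideocrop
Title: Water-Driven Crop Growth Simulation and Ideotype Calibration for
    Underutilised Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A daily-time-step, water-driven crop growth simulator in the
    AquaCrop tradition: canopy cover dynamics governed by growth and decline
    coefficients, a single-store root-zone water balance with
    evapotranspiration partitioned into soil evaporation and crop
    transpiration, biomass accumulation from normalized water productivity
    times cumulative normalized transpiration, and yield as biomass times a
    stress-adjusted harvest index. Ships grain-hemp, fibre-hemp and
    sugarcane-baseline ideotypes, a seeded synthetic-weather generator,
    RMSE-based model-performance grading, and a deterministic sequential
    (Boote-order) calibration procedure for adapting a baseline crop's
    parameters to a new crop from literature observations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
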