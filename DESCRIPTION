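Package: foragemap
Title: Core Foraging Areas from GPS Telemetry and Imaging Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delineating ungulate core foraging areas from GPS
    telemetry with time-local convex hulls (time-scaled distance, revisitation
    isopleths), for mapping grassland forage quantity (fresh-weight biomass)
    and quality (nitrogen content) from hyperspectral reflectance via
    band-ratio regression with leave-one-out validation and linear spectral
    unmixing, and for comparing species' foraging areas with multinomial
    logistic regression and calibration/discrimination diagnostics. Includes
    a synthetic-data module that generates trajectories, scenes, plot tables
    and species usage with known ground truth so every pipeline stage can be
    validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    nnet,
    polyclip,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    sp,
    pROC
Config/testthat/edition: 3
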