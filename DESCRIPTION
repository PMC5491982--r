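Package: breathcam
Title: Contactless Breathing Analysis from Thermal and Depth Camera Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating breathing rate and exhaled-air temperature
    trends from low-cost contactless sensors: adaptive calibration of thermal
    camera frames by recognising the printed temperature range in each frame's
    calibration bar with a shallow neural network, adaptive tracking of the
    mouth region from temperature-change maps, extraction of chest-motion
    series from depth matrices, FIR band-pass filtering and DFT spectral
    estimation of the breathing frequency, windowed trend features, recovery
    regressions and activity-response delays. Includes a synthetic paired
    thermal/depth scene generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
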