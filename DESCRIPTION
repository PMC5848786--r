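Package: canopygcc
Title: Canopy Greenness Time Series and Phenophase Transition Dates from
    Time-Lapse Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processes directories of time-lapse RGB canopy photographs into
    region-of-interest (ROI) colour statistics, green and red chromatic
    coordinate (Gcc, Rcc) time series, quality-controlled 1- and 3-day summary
    products, and phenophase transition dates with uncertainties. Includes
    solar-geometry and brightness quality filters, AICc-selected cubic
    smoothing splines with iterative asymmetric outlier rejection under a
    Laplace residual model, PELT changepoint segmentation into greenness
    rising and falling stages, amplitude-threshold transition date extraction
    with confidence intervals, camera sensor-response and reference-panel
    calibration utilities, and a synthetic-site generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
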