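Package: sifdown
Title: Canopy-to-Leaf Downscaling of Far-Red Solar-Induced Chlorophyll Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for downscaling far-red
    solar-induced chlorophyll fluorescence (SIF) at 760 nm from canopy to
    leaf level. Includes a diurnal synthetic-scene forward model with known
    per-pixel ground truth (clear-sky PAR course, crop-specific escape
    fraction dynamics, NPQ-like midday efficiency depression, top-of-canopy
    reflectance and at-sensor radiance around the O2-A absorption band), a
    spectral-fitting-method (SFM) SIF retrieval with effective
    surface-sensor-distance calibration on non-vegetated reference pixels,
    WDRVI-based fAPAR estimation, FCVI-based escape-fraction estimation and
    leaf-level SIF maps, emission-efficiency normalizations, and per-field
    diurnal statistics, canopy-leaf correlation and hysteresis analysis.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
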