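Package: paleowb
Title: Pollen-Based Holocene Water-Balance Reconstruction and Data-Model Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative paleoclimate reconstruction from fossil
    pollen assemblages and for comparing the reconstructions with gridded
    climate-model output. Implements modern-analog (MAT) and boosted
    regression-tree (BRT) pollen-climate transfer functions with squared-chord
    analog diagnostics and h-block cross-validation; bioclimatic indices
    (biotemperature, potential evapotranspiration, annual water balance,
    growing degree days); regional bootstrap synthesis of site reconstructions
    on a common time grid; SiZer trend maps and principal-component mode
    decomposition; Morlet wavelet analysis with red-noise significance; and
    EOF-truncated canonical correlation analysis between sea-level-pressure
    and moisture fields. A synthetic-data generator with known ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
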