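Package: rsstability
Title: Rank-Based Stability Analysis of Soil Respiration Spatial Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the long-term temporal stability of the
    spatial pattern of soil respiration (Rs) in grassland campaign surveys.
    Implements rank-based stability proxies (per-position mean rank and rank
    range across campaigns), a multi-scale "mixed scaling" terrain-attribute
    pyramid on digital elevation models (local mean elevation, elevation
    standard deviation, topographic position index, slope, northness,
    easterness), variogram estimation and model selection, ordinary kriging
    and kriging with external drift with leave-one-out cross-validation,
    scale-dependent correlation scans, a Gaussian bell-curve model linking
    mean rank to rank range, and a two-state equilibrium classification.
    Includes a synthetic-data generator emulating an undulating semi-arid
    grassland study design so the full pipeline runs end-to-end without
    field data.
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
    minpack.lm,
    purrr,
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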