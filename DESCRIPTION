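Package: sargox
Title: Sargassum-Driven Coastal Hypoxia: Oxygen Demand, Box Modelling and
    Monitoring Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and predicting hypoxia driven by decaying
    pelagic Sargassum in shallow tropical coastal waters. Implements a
    dissolved-oxygen mass-balance box model with residence-time exchange,
    diel gross primary production, temperature-dependent background
    respiration and a Sargassum biochemical-oxygen-demand term; estimates
    the per-biomass oxygen demand rate from bottle incubations with a
    random-slopes linear mixed-effects model; computes daily hypoxia
    durations from moored sensor time series on a four-level threshold
    ladder; and derives Sargassum percent cover from NDVI on two-band
    reflectance scenes. Seeded synthetic-data generators emulate each input
    so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
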