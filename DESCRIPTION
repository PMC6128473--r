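Package: wetscape
Title: Cross-Scale Phenology of Calling Amphibians, Wetland Hydrology, and
    Landscape Greenness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking ground-based wetland sensors to satellite
    composites in seasonally snow-covered landscapes. Detects species-specific
    anuran call signatures in hourly spectral summaries and derives first-call
    dates, site occupancy, calling phenophases and evening calling-activity
    integrands; reduces hourly water-depth logger series to daily medians and
    tests their association with precipitation-day counts by Spearman rank
    correlation; computes eight-day temperature integrands, growing degree
    units (base 10 degrees C, cap 30 degrees C) and climatograph water-balance
    classifications from daily station weather; and derives snow-free onset,
    NDVI green-up and evapotranspiration onset from 8-day and 7-day satellite
    composite series aligned to a common weekly calendar. A seeded synthetic
    multi-sensor generator with planted ground truth makes every stage
    testable end to end.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
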