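Package: gapscape
Title: Grid-Based Biodiversity Assessment and Protected-Area Gap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing terrestrial biodiversity from occurrence
    records in data-poor arid regions: species richness and endemicity
    mapping on a graticule grid, equal-variance partitioning of a
    standardized bioclimatic principal-component space into climatic
    clusters, per-species ecological profiling (elevation, climate
    envelope, land-cover distances), and a protected-area gap analysis
    with area-of-occupancy and extent-of-occurrence range estimators
    scored against the 17% and 12% conservation targets. Includes a
    virtual-ecologist simulator that generates complete synthetic study
    systems (correlated climate surfaces, elevation, land cover,
    protected areas, niche-driven occurrences) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
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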