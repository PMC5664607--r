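Package: fvcapacity
Title: Geospatial Capacity Modeling for Fruit and Vegetable Production Expansion
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A national crop site-suitability and food-availability pipeline.
    Identifies production centers for nutrient-dense fruit and vegetable crops
    from county acreage records, evaluates boolean raster overlays of monthly
    climate, soil, and land-use conditions to find suitable fallow cropland in
    and around those centers, expands center footprints by Euclidean buffer
    distances to form cropland-expansion scenarios, and converts suitable land
    area into loss-adjusted per-capita cup-equivalents of fruits and
    vegetables. Includes a synthetic-data generator that produces grid-aligned
    input bundles with analytically known ground truth so the full pipeline is
    testable without external geospatial downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    EBImage,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
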