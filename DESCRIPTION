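Package: cropharmony
Title: Harmonization of Subnational Crop Statistics Across Changing
    Administrative Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn raw, boundary-inconsistent subnational crop
    statistics into continuous, quality-flagged time-series of production,
    harvested or planted area, and yield. Implements screening rules that
    flag (never delete) high-yield outliers and low-variance runs, sub-crop
    re-aggregation, coverage-gated aggregation of fine-level statistics to
    coarser administrative units using a Gaussian-smoothed production
    climatology, detection and classification of administrative boundary
    changes with calibration of old-unit series onto current units (mean
    production shares for area-conserving splits, cropland-overlap
    dasymetric weights otherwise), conservation verification, and
    cross-validation of national annual totals against a reference series.
    Includes a fully ground-truthed synthetic scenario generator so every
    pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    polyclip,
    DBI,
    RSQLite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
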