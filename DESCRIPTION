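Package: ohigapfill
Title: Gapfilling, Provenance Tracking and Uncertainty Propagation for
    Composite Ocean Health Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An engine for hierarchical composite indicators in the style of
    the Ocean Health Index: reads tabular data layers and a region registry,
    estimates missing observations with a library of gapfilling methods
    (regional means with georegion fallback, territorial disaggregation,
    zero-filling, temporal and covariate regression, taxonomic rollups,
    nearest-donor grid interpolation), selects among candidate imputation
    models by leave-one-out cross-validation, records every filled value in a
    per-observation gapfilling ledger, and propagates the percent
    contribution of gapfilled data through the same weight tree used to
    aggregate status, trend, pressure and resilience into goal, region index
    and EEZ-area-weighted global scores. Includes seeded synthetic-data
    generators with known ground truth and Table-style reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
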