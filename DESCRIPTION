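Package: pvcrops
Title: Inventory, Nutrition, and Carbon-Sequestration Analytics for
    Perennial Vegetables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing cultivated perennial vegetables as a crop
    class: validation and categorical breakdowns of species-inventory
    tables (growth form, parts used, climate, domestication status),
    derivation of reference-anchored nutrient concentration classes from a
    benchmark crop set, multi-nutrient deficiency-syndrome scoring and
    superabundance analytics, and projection of carbon sequestration from
    future adoption under a 12-scenario grid. Includes a fully seeded
    synthetic-data generator for species inventories, multi-source nutrient
    measurement tables, and crop-area time series with known ground truth,
    plus report renderers mirroring the published table layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
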