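Package: habsuit
Title: Habitat Suitability and Quality Regionalization for Medicinal Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for regionalizing the habitat suitability of a
    medicinal plant from gridded ecological factors and field samples of
    chemical quality. Couples a presence-background maximum-entropy species
    distribution model (growth suitability, variable contributions, response
    curves) with fuzzy membership standardization of ecological factors
    against an equal-weight aggregative indicator of compound contents
    (quality suitability), weighted raster overlay, land-cover masking,
    three-class regionalization with area statistics, and root-mean-square
    error validation. Includes a synthetic-landscape generator with known
    ground truth so every stage is testable end to end, plus readers and
    writers for ESRI ASCII grids and point tables.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
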