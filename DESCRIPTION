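Package: forestprod
Title: Instantaneous Forest Woody Productivity from Two-Census Tree Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates species- and stand-level aboveground woody
    productivity from two-census forest plot data using instantaneous
    demographic-rate estimators based on the logarithmic-mean period
    biomass, fits lognormal power-law models of productivity against
    biomass with a mean-annual-temperature covariate, and decomposes
    why warm forests are more productive via two null-model
    projections (a species-response projection and a
    community-structure replaced-data resampling). Includes a
    synthetic forest-community generator with known ground truth for
    validating every stage of the pipeline.
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
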