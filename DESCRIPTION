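Package: extrisk
Title: Extinction-Risk Trend Assessment for Data-Limited Marine Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing extinction risk of data-limited marine
    species from relative-abundance survey indices. Fits a Bayesian
    exponential state-space model to one or more abundance indices via
    MCMC, extrapolates population change over three generation lengths,
    and maps the posterior of decline onto IUCN Red List Criterion A2
    categories. Also computes the Red List Index (globally and
    disaggregated by country using range-proportion matrices) and
    national conservation responsibility scores, and ships a seeded
    simulator for abundance indices, species assessment tables and range
    matrices so the whole pipeline can be exercised without confidential
    survey data. Includes the published Red List assessment table for
    the 70 shark and ray species endemic to the southwest Indian Ocean
    region as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
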