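Package: spatepi
Title: Spatial and Spatio-Temporal Analysis of Area-Level Event Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the spatial epidemiology of area-level event rates,
    built around the workflow used to study neighbourhood homicide rates:
    empirical Bayes rate smoothing, Jenks natural-breaks classification,
    kernel density surfaces of point events, global and Anselin local
    Moran's I with permutation inference, Kulldorff discrete-Poisson
    purely-temporal and space-time scan statistics with Monte Carlo
    inference, a correlation/VIF-gated variable-selection cascade, and
    geographically weighted regression (GWR) together with multiscale GWR
    (MGWR) calibrated by adaptive bisquare kernels and golden-section AICc
    search. Includes a synthetic-data module that generates polygon
    lattices, spatially autocorrelated covariates, spatially varying
    coefficient surfaces and Poisson space-time counts with implanted
    clusters, so the full pipeline is testable against known ground truth.
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
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
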