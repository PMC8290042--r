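Package: placeconn
Title: Place Connectivity from Geotagged Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes shared-user place connectivity from geotagged point
    events aggregated to polygon place layers: the place connectivity index
    (shared unique users normalized by the geometric mean of each place's
    user count), its directional variant, person-day movement matrices,
    distance-decay power-law fits, administrative boundary-effect
    regressions, focal-place association models, and inverse-connectivity
    agglomerative regionalization. Includes a gravity-model synthetic
    mobility generator so every pipeline stage can be exercised offline
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
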