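Package: landfrag
Title: Class-Level Landscape Fragmentation Metrics and Protected-Area
    Deforestation Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes class-level fragmentation metrics (edge density,
    clumpiness, area-weighted mean patch size and shape index) on categorical
    land-cover raster time series with three substantive classes (mature
    forest, non-forest, secondary forest), stratified by conservation-unit
    zones; tallies inter-map class transitions and the relative incidence of
    deforestation inside versus outside protected areas; and fits linear
    time trends by generalized least squares with ARMA error structure
    selected by a small-sample information criterion.  A seeded synthetic
    landscape-dynamics generator (contagious road-driven clearing, fishbone
    settlement geometry, irregular wildfire scars, fallow-regrowth
    succession) provides reproducible test landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nlme,
    mgcv,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
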