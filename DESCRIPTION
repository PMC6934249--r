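Package: metrogrid
Title: Dasymetric Population Gridding and Metropolitan Agglomeration
    Delineation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Disaggregates zone-level census population counts to a fine
    regular grid with a random-forest dasymetric model fitted on log
    population density, then delineates metropolitan agglomerations from
    the gridded surface by density thresholding, contiguity grouping with
    hole removal, minimum-area filtering, proximity-graph construction,
    and leading-eigenvector modularity community detection. Includes an
    urban size-class hierarchy tabulation, administrative urbanization
    shares, a synthetic landscape generator for testing, and plain-text
    raster (ESRI ASCII grid) and GeoJSON input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
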