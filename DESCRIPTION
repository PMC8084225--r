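Package: eaaforest
Title: Equal-Area Annulus Analysis of Neighbor Interactions in Forest Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects negative and positive density-dependent neighbor
    interactions in repeatedly censused forest dynamics plots with the
    Equal-Area Annulus (EAA) point-pattern method.  Neighborhood statistics
    (clustering, recruitment, mortality, growth) are computed in concentric
    annuli of identical area around every focal tree, compared against
    Monte Carlo null models generated by shuffling focal-tree attributes
    within species, and summarized as z-score curves and surfaces over
    physical and phylogenetic distance with penalized-spline smooths.
    Includes exact edge-effect correction, phylogenetic-distance quantile
    binning with tie shuffling, Benjamini-Hochberg adjustment, sensitivity
    (distance-manipulation) and species-removal protocols, and a seedable
    forest-plot simulator with plantable interaction effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
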