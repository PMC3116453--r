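Package: parkaccess
Title: Population-Weighted Distance Measures of Spatial Access to Parks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gravity-model (Huff) measures of potential spatial accessibility
    to parks. Computes, for each census block (or any demand point), the
    accessibility score of its k nearest parks, the Huff visit probabilities
    over that bounded choice set, and the population-weighted distance (PWD) -
    the expected travel distance to nearby parks. Supports geodesic and planar
    distance metrics with an Rcpp k-d tree for nearest-neighbour search,
    population-weighted aggregation over FIPS-like nesting hierarchies with
    subgroup and poverty/urban-rural stratification, a nearest-park baseline
    comparison (difference and Pearson correlation), within-stratum quintile
    classification of relative access, a seeded synthetic-landscape generator,
    and CSV/GeoJSON readers plus a pipeline runner with a reproducibility
    manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
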