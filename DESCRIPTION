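Package: peavigour
Title: Image-Based Early Vigour Phenotyping for Field Pea Seedlings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to derive early-vigour traits of field pea (Pisum
    sativum) seedlings from multi-view colour images and to analyse their
    dynamic growth. The package segments plant tissue from top- and
    side-view RGB images by colour rules, computes digital traits
    (estimated shoot biomass, top-view area, convex-hull area, canopy
    compactness, plant height), fits a continuous two-phase ("broken
    stick") linear growth model to biomass time series to locate the
    linear growth phase, and ranks genotypes with one-way ANOVA, Pearson
    correlations, relative growth rate, water-use efficiency and NDVI. A
    synthetic-scene and growth simulator with known ground truth makes
    the whole pipeline testable without access to a phenotyping platform.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
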