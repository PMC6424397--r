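Package: defoliatr
Title: Individual-Tree Defoliation Assessment from UAS Point Clouds and
    Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for quantifying pine processionary moth
    defoliation at individual-tree level in mixed pine-oak stands from
    photogrammetric products: ground classification by progressive TIN
    densification, digital terrain and canopy height models, local-maximum
    treetop detection with Voronoi crown delineation, NDVI/ExG threshold
    classification with shadow masking, per-tree defoliation scoring, and
    confusion-matrix/kappa/regression validation. Includes a synthetic
    stand generator with known ground truth so every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
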