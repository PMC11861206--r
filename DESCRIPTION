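Package: leafatlas
Title: 2D Leaf-Shape Phenotyping, Atlas Construction and Inbred-Line
    Identification from 3D Digitizer Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline turning structured 3D-digitizer point
    grids of maize ear leaves into area-preserving 2D leaf models and
    quantitative shape phenotypes. Grids (5 points per transect plus a tip
    point) are triangulated, screened within inbred lines, normalized,
    refined by sqrt(3) triangle subdivision and flattened to the plane by
    as-rigid-as-possible (ARAP) parameterization. From the flat models the
    package extracts 29 morphometric features (lengths, widths, angles,
    area, folding, radial contour descriptors), selects a minimally
    redundant semantic subset by correlation-distance clustering, tunes
    per-feature weights by a greedy grid search, ranks lines by a composite
    shape index into an atlas, and identifies inbred lines by weighted
    cosine similarity with Top-X accuracy evaluation. A parametric
    synthetic-leaf generator with known ground truth supports validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
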