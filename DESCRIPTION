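Package: bctdensity
Title: Breast Composition and Density Analysis for Spiral Breast CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies breast composition from dedicated prone-position
    (pendant-breast) spiral breast CT volumes. Segments each volume into
    air, adipose tissue, glandular tissue, skin, pectoralis muscle, rib and
    skin-fold classes, with the glandular class delineated by an adaptive
    region-growing algorithm whose acceptance rule tracks the running
    average breast density; localizes the four breast quadrants from the
    nipple landmark; and measures breast tissue volume (BTV), mammary gland
    volume (MGV) and percent breast density (PBD) for the whole breast and
    per quadrant. Includes a synthetic pendant-breast CT phantom generator
    with exact voxel-level ground truth, a tabular cohort simulator, age
    group summaries with Student t comparisons, and logarithmic and
    multiplicative-inverse age-regression models with residual standard
    error, including reconstruction of fits and residual error from grouped
    summary statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
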