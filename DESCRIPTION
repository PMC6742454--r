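Package: hemcyto
Title: Heterogeneous-Mixture EM Photometry for Low-Magnification Imaging
    Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies cell fluorescence and physical diameter from very
    low-magnification ("cell astronomy") fluorescence images in which each
    cell spans only 3-4 pixels. Bright spots are found with a sliding-window
    linear discriminant detector, each spot is fitted with a heterogeneous
    mixture (one bivariate Gaussian per cell plus a uniform background
    component) by an intensity-weighted expectation-maximization algorithm,
    per-cell fluorescence is read off the responsibility-weighted intensity
    sum and diameter off the full width at half maximum, and small cell
    clusters are resolved by recursive eigendecomposition-guided splitting
    with BIC-controlled stopping. A seeded simulator generates bead and cell
    fields with ground truth for calibration and validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
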