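Package: plotimpute
Title: Random-Forest Imputation of Forest Inventory Plots to Gridded Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes forest-inventory plot identifiers to every forested pixel of a
    gridded landscape by terminal-node co-occurrence voting over an ensemble of
    classification trees, one forest per response variable (canopy cover bin, canopy
    height bin, vegetation group). Includes the preprocessing rules for categorical
    landscape rasters (forest masking, vegetation-group recoding, bin-midpoint
    recoding, disturbance-layer collapse), derivation of plot-level attributes from
    tree records (overlap-corrected canopy cover, top-stratum height, basal-area
    dominant species, standing-dead counts), an accuracy-assessment suite (pixel-wise
    confusion matrices with user's and producer's accuracy, plot-footprint agreement,
    Kolmogorov-Smirnov disturbance analysis), and a seeded synthetic-landscape
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    jsonlite,
    knitr
Config/testthat/edition: 3
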