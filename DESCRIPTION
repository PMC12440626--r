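Package: nucexport
Title: Quantification of Pre-Mitotic Cyclin B Nuclear Export from
    Single-Cell Time-Lapse Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to measure the transient nuclear-export phase of
    mitotic cyclin B (Cdc13) in fission yeast from fluorescence
    time-lapse movies. Provides a ground-truth kinetic simulator and
    synthetic movie renderer, classical cell and nucleus segmentation
    (Gaussian blur plus Otsu thresholding), compartment
    concentration and amount decomposition with cytoplasm-by-subtraction,
    event-aligned ensemble analysis anchored to anaphase or spindle
    pole body separation, change-point estimation of export onset and
    stop times with transition-sharpness measures, and the population
    statistics used for cell-size homeostasis comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    deSolve,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2,
    knitr
Config/testthat/edition: 3
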