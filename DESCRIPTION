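Package: aeoscan
Title: Aeolian Desertification Monitoring from Reflectance Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for large-scale aeolian desertification monitoring from
    multispectral reflectance raster time series. Implements the Normalized
    Difference Desertification Index (NDDI), reference-curve matching by
    Mean Absolute Distance with p-tile threshold selection, a fine-to-coarse
    pure-pixel scale linkage built on a coarse grid frame, pan-sharpening
    (PCA, multiplicative, Brovey) with entropy and correlation quality
    metrics, and multispatial convergent cross mapping with bootstrap
    convergence tests for attributing desertified-area dynamics to climate
    and population drivers. Ships synthetic-scene and coupled-dynamics
    generators with known ground truth so the full pipeline is testable
    without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
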