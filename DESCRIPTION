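Package: phasorflim
Title: Phasor Analysis of Fluorescence Lifetime Imaging Microscopy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end phasor analysis of fluorescence lifetime imaging
    microscopy (FLIM) data: phasor transform of per-pixel time-binned
    decays, frequency-domain calibration against a monoexponential
    reference, intensity thresholding (custom, Otsu, multi-Otsu) and
    masked spatial filtering, level-set contour detection of regions of
    interest on the 2D phasor histogram, phase and modulation lifetime
    maps, two- and three-component fractional-intensity and molar-fraction
    decomposition, free/bound NADH metabolic fitting, Gaussian-mixture
    clustering of phasor clouds, distribution comparison with
    Kolmogorov-Smirnov and Mann-Whitney U tests, and trend fitting.
    Includes a synthetic-data generator, readers for a documented
    single-file container and the SimFCS-style '.ref' raster dialect,
    and a command-line pipeline producing tabular exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    mclust,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
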