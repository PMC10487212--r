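Package: chemmap
Title: Spatial Mapping of Chemical Composition in Fresh-Cut Fruit from
    Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning hyperspectral reflectance images of fresh-cut
    fruit slices into spatial distribution maps of chemical composition
    (moisture, soluble solids, titratable acidity, carotenoids).  Covers
    white/dark reflectance calibration, Savitzky-Golay smoothing, dual-sensor
    spectrum fusion, landmark-based planar image registration with circular
    region-of-interest extraction, availability-constrained wavelength
    selection by RReliefF ranking with correlation pruning and by
    correlation-based feature subset (CFS) search, replicate multilayer
    perceptron calibration models trained with Levenberg-Marquardt and
    early stopping, and pixel-wise prediction maps with region-wise error
    statistics.  Includes a synthetic-data generator emulating a
    multi-origin fruit sampling design so the whole pipeline is testable
    without proprietary image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    nnet,
    EBImage
Config/testthat/edition: 3
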