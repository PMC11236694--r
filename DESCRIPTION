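Package: hemospat
Title: Spatial Statistics for Hemocyte Localization in Fly Abdomen Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying the spatial distribution
    of fluorescently tagged hemocytes in cryosectioned Drosophila abdomens.
    Provides a synthetic-data generator (jittered-ellipse section windows,
    point patterns under complete spatial randomness, center-biased thinning
    or Thomas cluster processes, and Gaussian-blob fluorescence rendering),
    image segmentation (Yen entropy thresholding, background suppression,
    watershed cell detection, feature export), spatial point-pattern
    statistics (equal-area percentile annuli around the section centroid,
    centroid-distance ECDF curves with confidence bands, pairwise-distance
    histograms, Delaunay neighborhood summaries, k-nearest-neighbor
    G-functions, pooled 2D coordinate histograms), and nonparametric
    fed-versus-starved comparison with per-fly averaging, section-area
    quality control and exact Mann-Whitney U tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    mgcv,
    deldir,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
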