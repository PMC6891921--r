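Package: vesselquant
Title: Quantification of Microvessel Networks, Permeability and Leukocyte
    Extravasation from Confocal Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for 3D in vitro microvessel experiments imaged by
    confocal microscopy. Provides a synthetic phantom generator with exact
    ground truth (tubular networks, dextran leakage time-lapse, migrating
    leukocyte-like particles), the preprocessing chain used for vessel
    segmentation (maximum-intensity projection, outlier removal, Gaussian
    smoothing, binarization), skeleton-based network morphometry (area
    coverage, branch lengths, diameters, junction/endpoint connectivity
    ratio), an apparent-permeability estimator from extravascular tracer
    intensity rise, nearest-neighbour particle tracking with extravasation
    fate classification, and the statistical post-processing used for group
    comparison (control normalization, min-max scaling, ANOVA with Tukey
    contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
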