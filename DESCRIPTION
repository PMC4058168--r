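Package: cartwave
Title: Spatiotemporal and Spectral Mapping of Carotid Artery Wall Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated characterization of carotid-artery wall motion from
    B-mode ultrasound image sequences. Segments the moving vessel wall using
    spatial texture features (neighborhood mean, standard deviation, entropy)
    plus a temporal-variability feature and k-means clustering, tracks the
    lumen-wall boundary with sub-pixel precision, extracts radial-distension
    signals in midway-overlapping regions of interest along the wall, and
    assembles spatiotemporal and spatiospectral 2D maps of the wall's wavy
    motion. Two spectral homogeneity features (a double-Fourier-transform
    area and a ramp-weighted area under the envelope of the across-ROI
    spectral standard deviation) support threshold-based screening of
    healthy-young-like, healthy-elderly-like and pathological-like motion.
    Includes a synthetic pulsating-vessel phantom generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
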