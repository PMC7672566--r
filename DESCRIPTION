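Package: astronet
Title: Calcium Event Detection and Functional Astrocyte Network Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of time-lapse fluorescence calcium imaging of
    astrocyte cultures: noise-calibrated extraction of discrete calcium events
    from paired activity and cell-free image stacks (offset subtraction, 3-D box
    denoising, per-pixel baseline and adaptive thresholding, spatiotemporal
    clustering, watershed cell segmentation), per-culture activity statistics
    (oscillation frequency and duration, fraction of working cells, spectral
    energy percentile frequency bounds), and reconstruction of a lag-aware
    functional network in which nodes are astrocytes and edges mark
    above-threshold maxima of the lagged uncentered correlation between
    detrended per-cell calcium signals. Includes a seeded synthetic-movie
    generator with ground-truth cells, events and coupling graphs for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    EBImage,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
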