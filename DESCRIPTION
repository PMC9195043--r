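Package: VerteTrack
Title: Markerless 2D Vertebral Motion Tracking from Intrafraction kV Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markerless intrafraction motion monitoring for paraspinal
    stereotactic body radiotherapy. Single kV projections acquired during
    treatment are matched against same-day cone-beam CT reference
    projections by maximizing a normalized cross-correlation objective
    inside a per-angle vertebral region of interest, optimized by a 2D
    downhill simplex with warm starts, simplex rebuilds, and a
    capture-range penalty. Includes a synthetic thorax/spine phantom and
    cone-beam digitally-reconstructed-radiograph renderer, frame
    qualification filters, a headless tracking-session state machine, and
    an evaluation harness reproducing phantom translation and rotation
    test protocols with per-triplet repeatability statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    jsonlite,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
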