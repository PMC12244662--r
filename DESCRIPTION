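Package: compassFusion
Title: Multimodal Medical Image Fusion with Gradient-Compass Edges and
    Variable-Order Fractional Multi-Objective Darwinian PSO
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pixel-level fusion of co-registered grayscale medical image
    pairs (e.g. CT and MR). Edge content is extracted with an
    eight-direction Sobel gradient compass, modality-exclusive detail
    images are formed, and per-pixel fusion weights are derived from
    windowed covariance eigenvalue sums. A variable-order fractional
    multi-objective Darwinian particle swarm optimizer (VF-MODPSO) tunes
    the weight-map parameters against a bi-objective of fused-image
    quality (entropy, feature mutual information, edge preservation) and
    computational cost, maintaining a bounded Pareto archive with
    crowding-distance pruning. Includes the quality-indicator suite
    (entropy, mutual information, FMI, Qabf, SSIM, IGD, hypervolume), a
    seeded synthetic CT/MR phantom generator, and image I/O for
    PNG/TIFF/PGM.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
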