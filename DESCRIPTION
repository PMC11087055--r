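Package: polonaise
Title: Simulation and Quantification of Vortex-Like Tissue Flows in the
    Early Amniote Embryo
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the bilateral counter-rotating
    ("polonaise") cell flows of the pre-gastrula amniote epiblast from
    time-lapse microscopy. Provides a synthetic tissue-flow generator with
    ground-truth tracer trajectories and rendered fluorescence movies, a
    from-scratch two-pass windowed cross-correlation particle image
    velocimetry (PIV) engine with vector validation and calibration,
    velocity-field analysis (time averaging, vorticity, divergence,
    streamlines, trajectory projections), detection of counter-rotating
    vortex pairs with separation and persistence metrics, grid-based
    labeled-nucleus quantification, and an end-to-end pipeline with group
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
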