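Package: deformsense
Title: Motion-Energy Modelling of Dynamic Deformation Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates how the visual system detects dynamic deformation of
    object contours. Renders deforming-bar stimuli and moire-illusion stimuli
    (a static bar over a tilted drifting grating), passes them through a
    V1-style spatiotemporal motion-energy stage and an MT-style
    direction-selective stage (half-wave rectification, divisive
    normalization, Gaussian spatial pooling, opponent cosine direction
    weighting), and scores the resulting direction-response maps with a
    higher-order sinusoidal kernel via zero-mean normalized cross-correlation
    (ZNCC). Kernel scores are linked to deformation-report proportions by
    exponential fitting and r-squared model comparison, with a seeded
    synthetic-observer simulator and trial-schedule builders for the
    psychophysical designs.
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
    tiff,
    withr,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
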