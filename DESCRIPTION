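Package: flexbeam
Title: Aligned Peak Response Beamforming for Flexible Ultrasound Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs B-mode ultrasound images from flexible (deformable)
    array transducers whose element geometry is unknown, using the Aligned
    Peak Response (APR) delay estimator: per-scanline and per-element time
    delays are recovered by aligning the strong peak echoes of fiducial
    markers embedded in an assistant structure placed on the skin, without
    any external shape sensing.  Includes a desk-scale time-of-flight RF
    channel-data simulator for point-target and scatter phantoms, an
    artificial-curvature transform that re-delays flat-acquisition RF data
    to mimic a deformed probe, a geometry-aware delay-and-sum reference
    beamformer with dynamic or fixed receive focusing, and image-quality
    metrics (FWHM, CNR, PSNR, location error, delay-curve error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    png,
    optparse,
    knitr
Config/testthat/edition: 3
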