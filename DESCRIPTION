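Package: ddlampr
Title: Smartphone Digital Droplet LAMP Video Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for digital droplet loop-mediated isothermal
    amplification (ddLAMP) assays imaged as fluorescence video of droplets
    flowing through transparent tubing. Frames are denoised, background
    subtracted against a median frame, droplets are detected with a circle
    Hough transform, refined by morphological opening, sized by their largest
    chord, and quantified in CIE-xyY luminance after gamma correction and a
    linear RGB to XYZ transform. Per-frame detections are linked into tracks
    so each physical droplet is counted once, droplets are classified against
    a twice-negative-control luminance threshold, and the positive fraction
    is converted to an absolute target concentration by Poisson statistics
    with exact binomial confidence intervals. Includes a synthetic assay
    generator (Poisson-partitioned droplets rendered as anti-aliased video
    with per-droplet ground truth) and a desk-scale simulation of the
    isothermal heater's PID control loop with Ziegler-Nichols tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    matrixStats,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
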