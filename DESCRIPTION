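Package: sonocaliper
Title: Automatic Caliper Placement for Cyst Measurement in B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage pipeline that detects renal cysts in B-mode
    ultrasound images and places a pair of measurement calipers (salient
    landmarks) on each cyst's longest diameter.  A grid-based detector
    proposes bounding boxes; each box is expanded, cropped and fed to a
    nested-U convolutional network that regresses a two-channel inverted
    Gaussian saliency map, whose per-channel minima are decoded into the
    two caliper points.  A plausibility gate compares caliper distance
    with box size and repairs implausible pairs by point reflection about
    the box centre.  Includes the full evaluation protocol (circle
    intersection-over-union matching, precision/recall, position error
    and diameter length error), a seeded synthetic speckle phantom
    generator with known ground truth, detection losses (generalised IoU,
    confidence and classification cross-entropy) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
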