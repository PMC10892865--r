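Package: CornealGaze
Title: Calibration-Free Corneal-Imaging Gaze Estimation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometry and image-analysis toolkit for calibration-free mobile
    eye tracking by corneal imaging. A per-user 3D eyeball model (sphere of
    fixed 12 mm radius) is fitted by Gauss-Newton to points triangulated from
    pupil-boundary correspondences seen by an infrared and an RGB eye camera.
    The model maps pupil detections point-to-point from the IR to the RGB eye
    image by ray-sphere intersection, the corneal reflection patch is cropped
    and mirrored, and a RANSAC-estimated homography against the front-scene
    camera transfers the pupil centre into scene coordinates as the point of
    gaze. Includes a classical pupil detector, a corner/patch feature matcher,
    angular-error evaluation with per-participant aggregation, and a fully
    deterministic synthetic-session generator with ground truth so the whole
    pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
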