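Package: beetrackr
Title: Tracking-by-Detection and Evaluation for Dense Honey Bee Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for multi-object tracking-by-detection of honey bees in
    observation-hive imagery. Provides a constant-velocity Kalman filter with
    IoU-gated Hungarian association and track lifecycle management that
    consumes per-frame instance-segmentation detections (bounding box, mask
    polygon, confidence score), readers and writers for COCO-dialect
    annotation files and MOTChallenge text, letterbox coordinate transforms
    and frame-rate downsampling, an evaluation stack (instance-segmentation
    average precision, CLEAR MOT, MOTS), a synthetic dense-swarm scene
    generator with a configurable detector-noise model, and per-track
    trajectory extraction with activity classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
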