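Package: paniclepipe
Title: Planting-Row Detection and Head-Density Mapping from Crop-Head
    Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Turns per-image bounding-box detections of grain heads
    (sorghum panicles) from UAV or ground imagery into planting-row models
    fitted by iterative RANSAC, a GPS-anchored quasi-mosaic composite of
    the whole field, and head-density statistics: per-row linear densities,
    per-image areal densities, along-row gap records, and field-wide
    moving-sum density maps with sum-one Gaussian smoothing.  Includes a
    synthetic-field simulator (parallel planting rows, Poisson head
    placement, overlapping camera footprints, detector noise) so that
    every stage can be validated against known ground truth, plus the
    standard object-detection evaluation metrics (IoU matching, average
    precision at a fixed IoU threshold, count MAE/RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
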