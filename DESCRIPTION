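Package: foxwatch
Title: Camera-Based Posture, Activity and Behavior Monitoring for Singly Housed Foxes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processing pipeline for per-frame object-detector output
    from enclosure cameras observing a single red fox. Turns detection
    streams (posture class, confidence, normalized bounding box) into
    per-second activity levels via windowed bounding-box displacement,
    fuses two opposing cameras, smooths postures with a sliding-mode
    filter, counts posture changes, classifies behavior with a
    posture-by-activity decision tree, and aggregates time budgets.
    Also provides detector-evaluation metrics (IoU, precision, recall,
    11-point interpolated average precision, mAP), readers for
    YOLO/Darknet and Pascal-VOC annotations, and a ground-truthed
    behavior simulator so the whole pipeline is testable without video
    or trained network weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    ggplot2
Config/testthat/edition: 3
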