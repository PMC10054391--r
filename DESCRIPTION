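Package: pupwatch
Title: Behavior-Based Summarization of Dog Monitoring Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable pipeline for behavior-based summarization of
    single-dog monitoring video from per-frame object detections.
    Detection postprocessing links per-frame dog and person detections
    into tubelets, bridges short runs of missed detections by gap-limited
    tubelet linking with linear box interpolation, retrieves dog-alone
    frame sequences, crops them with a unified padded bounding box, and
    orchestrates two-stream (appearance plus motion) behavior recognition
    behind pluggable model backends with deterministic mocks. Behavior
    and location logs are summarized into episodes, poor-welfare
    indicators with threshold alerts, and visual summaries (gauges,
    occupancy heatmap, trajectory, nested behavior proportions,
    timeline). A synthetic scenario generator renders frames and
    detection streams with known ground truth so every stage is testable
    without video data or trained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    EBImage,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
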