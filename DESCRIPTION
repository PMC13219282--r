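Package: fsodbench
Title: Few-Shot Object Detection Benchmarking for Optical Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for constructing and scoring few-shot object detection
    benchmarks on bounding-box annotated microscopy images. Provides a
    certified-exact two-phase integer-programme optimizer that partitions
    multi-source image pools into reference and support splits, selection
    among optimal splits by the Support-Spread Score (class-presence
    coverage times normalized class-balance entropy), a Hungarian-matching
    detection evaluator (mean F1 over a 50-point IoU threshold sweep and
    mean IoU of true positives at 0.5), non-maximum suppression, a cascaded
    crop-and-classify few-shot detection pipeline with a pluggable
    classifier, COCO-style annotation and detection I/O, and a seeded
    synthetic microscopy image generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
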