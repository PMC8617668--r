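Package: skywatch
Title: Small-Bird Detection and Evaluation for Sky-Surveillance Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting small flying birds in high-resolution
    grayscale sky-surveillance video, of the kind recorded by upward-facing
    monochrome cameras around wind farms. Implements a classical
    background-subtraction detector (running-average background model,
    morphological-gradient gain compensation, Gaussian smoothing, blob
    detection and area filtering), tiled-inference coordinate re-projection
    and temporal frame stacking front-ends for single-shot neural detectors,
    k-means anchor-box estimation, multi-model ensemble voting (affirmative,
    consensus, unanimous), and Pascal-VOC exact-AUC mAP plus COCO-style
    101-point AP50 evaluation. A synthetic sky-scene generator and a
    configurable simulated detector allow the whole pipeline to be exercised
    end-to-end without field data or a trained network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    EBImage,
    igraph,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
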