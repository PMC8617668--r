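# skywatch

Detection and evaluation toolkit for small birds in high-resolution
grayscale sky-surveillance video — the kind recorded by upward-facing
monochrome cameras around wind farms to monitor collision risk. Birds in
such footage are tiny (frequently under 500 px² in a 3840×2160 frame),
change apparent size as they fly, and appear against skies that range from
near-static to dominated by drifting clouds and illumination changes.

The package implements, as composable tibble-in / tibble-out functions:

* **A classical background-subtraction detector** — running-average
  background model `B ← (1−α)B + αI`, foreground `D = |I − B|`,
  morphological gradient (dilation − erosion) for gain compensation,
  Gaussian blur (kernel 9), 8-connected blob detection, and an inclusive
  blob-area filter. Every intermediate image is inspectable.
* **Tiled-inference geometry** — exact-partition tiling of a 4K frame
  into 1920×1080 tiles, and bijective re-projection of detections from a
  square network resolution (default 1024) back to global coordinates.
* **Temporal stacking** — frames (t−1, t, t+1) as the three channels of
  one detector input; an N-frame sequence yields N−2 stacks.
* **Anchor estimation** — seeded k-means (k = 9) on ground-truth (w, h)
  pairs, centroids rounded and sorted by area, printed in darknet
  `(w,h) (w,h) …` form.
* **Ensemble voting** — greedy IoU grouping of detections from k models
  with one-vote-per-model, then *affirmative* (any model), *consensus*
  (strict majority, ≥ 4 of 6) or *unanimous* (all k) selection.
* **Evaluation** — greedy VOC-style matching at IoU ≥ 0.5 (precision
  `TP/(TP+FP)`, recall `TP/(TP+FN)` at a 0.25 objectness gate), exact
  area-under-envelope VOC mAP, and 101-point COCO AP50.
* **A synthetic sky generator and simulated detector** — dark elliptical
  birds with a calibrated size mixture (~42 % of boxes under 500 px²)
  over a static or dynamic (fractal cloud field + illumination drift)
  sky, with tight ground-truth boxes; plus a miss/jitter/false-positive
  detector model. Everything is seeded and byte-reproducible, so the
  whole pipeline runs end-to-end with no field data, GPU, or trained
  weights.

File formats: darknet-txt and Pascal-VOC-XML annotations, line-delimited
JSON detection records, PNG/ASCII-PGM frame sequences. A thin CLI over
the same functions lives at `inst/scripts/skywatch.R`
(`simulate | detect | mock-detect | anchors | ensemble | eval | pipeline`).

## Worked example

Simulate a dynamic-sky scene, run a six-fold simulated detector ensemble,
vote by consensus, and evaluate:

```r
library(skywatch)

scene <- generate_sequence(sky_preset("klim", n_frames = 30, seed = 7))
folds <- dplyr::bind_rows(lapply(1:6, function(m)
  simulate_detector(scene$gt,
    sim_detector_config(miss_rate = 0.2, fp_rate = 0.5, seed = 100 + m),
    frame_w = 960, frame_h = 540, source_id = paste0("fold", m))))
merged <- ensemble_detections(folds, "consensus", k = 6)
evaluate_detections(merged, scene$gt)
#> <sky_eval> 200 detections vs 240 ground truths (IoU >= 0.50)
#>   counts @ conf >= 0.25: TP 200  FP 0  FN 40  P 1.000  R 0.833
#>   confidence sweep:      VOC mAP 0.8333  COCO AP50 0.8317
```

With each fold missing 20 % of birds independently, consensus voting
(≥ 4 of 6 folds) discards every unreplicated false positive — hence
precision 1.000 — at the cost of recall: 0.833 here, a little under the
binomial ceiling of 0.901 for ≥ 4 successes at p = 0.8 because jittered
boxes of the smallest birds sometimes fall below the 0.5 grouping IoU and
split their votes. VOC mAP (exact area under the
monotone precision–recall envelope) and COCO AP50 (101-point
interpolation of the same envelope) agree to a few thousandths, as they
must once a run has more than ~50 ground truths. `tidy()`, `glance()` and
`autoplot()` give the metrics as tibbles and the PR curve as a ggplot.

Anchor priors for this scene:

```r
estimate_anchors(scene$gt, k = 9, seed = 0)
#> <anchor_set> (7,8) (12,11) (16,18) (22,26) (28,22) (29,33) (39,33) (36,44) (45,39)
```

The classical detector's background sensitivity, on two scenes with
byte-identical birds:

```r
compare_backgrounds(sky_scene_config(n_frames = 40, seed = 11))
#>   background n_det  tp   fp fn    recall recall_min_area
#> 1     static   287 274   13  6 0.9785714       0.9785714
#> 2    dynamic  6337 269 6068 11 0.9607143       0.9607143
```

On a near-static sky, background subtraction finds 98 % of birds with a
handful of false positives; drifting textured clouds raise the
false-positive count by two orders of magnitude at identical settings —
the failure mode that motivates learned detectors for this problem.

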