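---
title: "Methods: detection, evaluation and simulation in skywatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, evaluation and simulation in skywatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skywatch)
```

## The problem

Upward-facing monochrome cameras around wind farms record high-resolution
(nominally 4K, ~5 fps) video of open sky in order to monitor birds flying
near the turbines. Detection is hard for three compounding reasons: birds
span a tiny fraction of the frame (often well under 500 px^2 in a
3840x2160 image), their apparent size and shape change as they approach or
recede, and the background is not static — cloud banks drift through the
field of view and overall illumination changes with weather and time of
day.

`skywatch` packages the building blocks of a detection-and-evaluation
pipeline for this setting: a classical background-subtraction detector;
tiling and temporal-stacking front-ends of the kind used to feed
single-shot neural detectors; k-means anchor estimation; multi-model
ensemble voting; VOC/COCO-style evaluation; and a synthetic scene
generator plus a simulated detector so that every stage can be exercised
and tested end-to-end without field data or a trained network.

All geometry uses one convention: 0-based pixel coordinates and half-open
boxes, so a box `(x, y, w, h)` covers `[x, x+w) x [y, y+h)` and has area
exactly `w * h`. File readers and writers convert to and from the darknet
(normalised centre) and Pascal-VOC (1-based inclusive corner) dialects at
the format boundary only, which keeps the classic off-by-one drift out of
the core.

## The classical detector

The background-subtraction detector processes each grayscale frame `I`
through five stages, each inspectable via `detect_frame()`:

1. **Background subtraction.** A per-pixel background estimate `B` is
   maintained as a running average, `B <- (1 - a) B + a I`, and the
   foreground map is `D = |I - B|`. The effective rate is
   `a = max(alpha, 1/n)` after `n` frames: during warm-up the model is the
   cumulative mean of all frames seen, so anything present only in the
   first frames (including birds) decays like `1/n` rather than lingering
   as a ghost at the initial learning rate; afterwards the model is an
   exponential average with rate `alpha` (default 0.05) that tracks slow
   illumination changes.
2. **Gain compensation.** The morphological gradient (dilation minus
   erosion, square 3x3 structuring element) of `D`. A spatially uniform
   intensity shift — the signature of a camera gain or exposure change —
   has zero gradient, while compact blobs keep strong local contrast.
3. **Noise removal.** Gaussian blur with a kernel of size 9. Since only a
   size is specified, the bandwidth follows the common size-derived rule
   `sigma = 0.3 ((k-1)/2 - 1) + 0.8`, and the convolution uses replicate
   edge padding so constants are preserved exactly.
4. **Blob detection.** Binarise at an intensity threshold (default 15 of
   255, roughly 3 sigma above the blurred sensor-noise floor) and extract
   8-connected components; each is summarised by its centroid and the
   equivalent-circle radius `sqrt(area / pi)`.
5. **Area filter.** Components with equivalent-circle area inside an
   inclusive user-defined window (default 36–5000 px^2) are emitted as
   detections. 36 px^2 is the smallest bird size category that occurs in
   this kind of footage; the upper bound rejects cloud banks. The reported
   box is the bounding square of side `2 * radius` centred on the
   centroid, with confidence fixed at 1.0 so the output passes the
   objectness gate of evaluation code unchanged.

This method uses no size, shape or colour priors beyond the area window —
that is both its appeal (no training data) and its weakness. On a
near-static sky it localises birds well; on a dynamic sky the frame
difference is dominated by cloud motion and the detector produces false
positives in proportion to the cloud texture that survives the gradient
and blur. `compare_backgrounds()` runs the controlled experiment: two
scenes with byte-identical bird trajectories, one static and one dynamic
background, same detector config. With package defaults the dynamic scene
yields a false-positive count two orders of magnitude above the static
scene while static-scene recall for birds of at least 36 px^2 stays above
0.9 — the qualitative failure mode that motivates learned detectors in
this domain.

**Scoring the classical detector.** Its boxes are equivalent-circle
squares whose scale is set by the blur kernel, not by the bird's true
extent, so IoU against tight ground-truth boxes understates localisation.
`compare_backgrounds()` therefore scores it by centre distance
(`match_by_center()`: a hit if the detection centre falls within
`max(3, r_gt)` pixels of an unmatched ground-truth centre, `r_gt` the
ground truth's equivalent-circle radius). The IoU-based evaluation module
remains the standard for detectors that predict tight boxes.

## Front-ends for single-shot detectors

**Tiling.** Resizing a 4K frame to a network resolution of 1024x1024
shrinks small birds below the smallest anchor prior. `tile_layout()` /
`tile_frame()` split the frame into an exact partition (default 2x2, so
four 1920x1080 tiles) that is processed tile by tile, and
`map_to_global()` re-projects network-space detections back: scale by
`tile_w / network_size` and `tile_h / network_size` independently (plain
anisotropic stretch — no letterboxing, matching the resize convention of
the darknet family), then translate by the tile offset.
`merge_tile_detections()` concatenates per-tile results; optional
cross-tile non-maximum suppression exists but is off by default, because
the tiling scheme deliberately does not handle birds that straddle a tile
boundary (they are assumed rare and transient at 5 fps).

**Temporal stacking.** `temporal_stack()` packs frames `t-1, t, t+1` as
the three channels of one input, giving a single-shot detector short-range
motion cues without explicit tracking. Channels carry raw intensities (no
differencing, no normalisation). `stack_sequence()` yields `N - 2` stacks
for an `N`-frame sequence: the first and last frames have no complete
neighbourhood and are excluded.

**Anchors.** `estimate_anchors()` clusters ground-truth `(w, h)` pairs
with k-means (Euclidean distance on the raw dimensions, `k = 9`, seeded,
`nstart = 10`) and returns integer centroids sorted by area — the
standard anchor complement for a three-scale single-shot head. When fewer
than `k` distinct shapes exist the most frequent shapes are repeated, so
the contract of exactly 9 anchors always holds.

## Ensemble voting

Cross-validation folds of the same detector make correlated but distinct
mistakes; voting across k folds trades precision against recall.
`group_detections()` clusters the pooled per-frame detections greedily:
highest-confidence unassigned detection seeds a group, which absorbs from
every *other* model its best-overlapping unassigned detection with IoU to
the seed of at least `group_iou` (default 0.5). One member per model per
group prevents double-voting; a model's second box near the same object
seeds its own group. `vote_detections()` then keeps a group under

* *affirmative* — any model suffices (vote count >= 1),
* *consensus* — a strict majority (> k/2, i.e. at least 4 of 6; "half"
  exactly is read as not a majority),
* *unanimous* — all k models.

The kept group is emitted as its highest-confidence member's box with the
mean member confidence. By construction the three outputs nest
(unanimous ⊆ consensus ⊆ affirmative), so recall is ordered
affirmative >= consensus >= unanimous whenever the folds miss objects
independently; which strategy wins on mAP depends on the false-positive
rate, since affirmative also admits every singleton mistake.

## Evaluation

`pr_curve()` pools detections across frames, ranks them by descending
confidence (ties keep input order) and matches greedily within each
frame: a detection is a true positive if its best IoU over not-yet-matched
ground truths reaches the threshold (default 0.5). Two summaries of the
curve are provided:

* `voc_map()` — the exact area under the monotone precision envelope
  (precision at recall `r` replaced by the maximum precision at any recall
  `>= r`), integrated as rectangles between successive recall values.
  With a single class, mAP equals this AP.
* `coco_ap50()` — the envelope averaged at the 101 recall points
  `0.00, 0.01, ..., 1.00`. Its discretisation error relative to the exact
  area is at most about 1/(2 * n_gt) per recall step, which is why the two
  metrics agree closely once a run has more than ~50 ground truths.

Only the IoU 0.5 working point is exposed: for objects a few pixels
across, a stricter overlap (e.g. 0.75) mostly measures localisation
jitter rather than detection, and small-object pipelines are conventionally
compared at AP50.

`evaluate_detections()` reports both working modes side by side: TP/FP/FN
counts with precision and recall at a fixed objectness gate (default 0.25,
the conventional single-shot deployment threshold), and the gate-free
confidence-sweep metrics. The distinction matters: a detector whose
confidences all sit below the gate counts zero TP yet can still sweep a
perfect PR curve.

## The synthetic scene generator

`generate_sequence()` emulates the statistical structure of this footage,
not its photometric detail:

* **Birds** are dark ellipses inscribed in integer-aligned boxes, flying
  along straight lines with a small Gaussian heading drift (sd 0.05
  rad/frame), reflecting at frame borders, at 3–8 px/frame. Box areas are
  drawn from a two-piece log-uniform mixture calibrated so that a
  configurable fraction (default 1000/2400 ≈ 42%) falls below a cutoff
  (default 500 px^2) — the headline size statistic of the wind-farm
  footage this emulates. Each track lasts `lifespan_frames` (default 3
  frames, about 0.6 s at 5 fps — the short end of plausible visibility
  for birds near the resolution limit; short tracks also make a 2400-box
  annotation set carry ~800 independent size draws, so the calibrated
  fraction is reproduced to about one percentage point). The ground-truth
  box is exactly the tight box of the darkened pixels.
* **Static skies** are a fixed smooth vertical gradient (mean level 170)
  plus per-frame Gaussian sensor noise (sd 2).
* **Dynamic skies** add a multi-octave (fBm-style) value-noise cloud
  field with features from 64 px down to 4 px, advected across the frame
  at `cloud_speed` px/frame, scaled to a peak-to-peak contrast of 60
  intensity levels (bright textured cumulus against clear sky in
  monochrome), plus a global illumination drift of 0.5 intensity/frame.
  The fine octaves matter: a cloud field smooth at the morphology scale
  would be suppressed by the detector's gradient stage, and real cloud
  banks are not smooth.
* **Controlled comparisons.** Bird trajectories and backgrounds are drawn
  from separate RNG streams derived from the config seed, so two configs
  differing only in `background_mode` render identical birds.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: bird articulation (wing beats), motion blur,
perspective size change within a track, vignetting and lens distortion,
compression artefacts, and real cloud morphology. The generator supports
the claim that the pipeline's machinery is correct and that background
dynamics degrade frame differencing; it cannot support absolute accuracy
claims for any real site.

`simulate_detector()` is the corresponding stand-in for a trained
detector: each ground truth is missed independently with `miss_rate`,
survivors get Gaussian positional jitter and ±10% size jitter (suppressed
entirely when `jitter_sigma = 0`, so a noise-free config reproduces the
ground truth exactly), and Poisson false positives per frame are placed
uniformly with their own confidence range. It makes ensemble and
evaluation behaviour testable against closed-form expectations (binomial
recall, Poisson false-positive counts).

## Numerical and design choices

* Half-open integer pixel geometry: IoU on integer boxes equals a
  rasterised pixel count exactly, which the tests exploit.
* Greedy matching in descending confidence with best-IoU assignment and
  single-use ground truths — the standard VOC protocol. Equal confidences
  break by input order, deterministically.
* Connected components are 8-connected (a diagonal chain of pixels is one
  blob).
* Grayscale morphology is computed on intensities rescaled to `[0, 1]`
  and mapped back, so arbitrary intensity scales are handled exactly.
* The blob binarisation threshold is inclusive (`>=`), as is the area
  window.
* Background-model warm-up: detections from the first `warmup` frames
  (default 5) of a sequence are discarded; by then a first-frame transient
  has decayed to a fifth of its contrast, below the default binarisation
  threshold for typical bird contrasts.
* k-means on raw `(w, h)`: anchor estimation follows the "cluster the
  dimensions" convention; IoU-distance variants exist in the literature
  but are not what this pipeline family uses by default.
* Ensemble representative box = highest-confidence member (not a box
  average); confidence = mean over members.
* Detection files are line-delimited JSON with a schema tag and 17
  significant digits, so write-read round trips are bit-exact and repeated
  pipeline runs are byte-identical.

## Problem sizes used by the test suite

The suite and the acceptance script run at desk scale by choice: scenes of
960x540 (tiling checks use full 3840x2160 frames), 30–60 frames, 8–40
simultaneous birds, giving 240–2400 ground-truth boxes per experiment;
oracle fuzzing uses 1000 random box pairs and 200 random PR instances.
These sizes put binomial standard errors well inside the asserted
tolerances while the whole suite runs in about a minute.

## Limitations

The classical detector's boxes are nominal (equivalent-circle squares), so
its IoU-based mAP is pessimistic; compare it by centre distance or accept
the bias. Tiling drops nothing but also merges nothing at boundaries by
default, so a bird on a tile seam can be reported twice or half-sized.
The ensemble grouping is a greedy stand-in for the published
detection-ensembling procedures; it is deterministic and documented but
not identical to any specific library. And all accuracy statements in the
tests are statements about the synthetic scenes described above.
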