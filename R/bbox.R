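#' Construct a tibble of bounding boxes
#'
#' Boxes use the package-wide pixel convention: 0-based coordinates and
#' half-open extents, so a box covers the pixel region
#' `[x, x + w) x [y, y + h)` and its area is exactly `w * h`. All functions
#' in the package share this convention; file readers convert at the format
#' boundary.
#'
#' @param x,y Left and top edge in pixels (0-based). Vectorised.
#' @param w,h Width and height in pixels; must be strictly positive.
#' @return A tibble with columns `x`, `y`, `w`, `h`.
#' @examples
#' bbox(0, 0, 10, 10)
#' @export
bbox <- function(x, y, w, h) {
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        w = as.numeric(w), h = as.numeric(h))
  validate_boxes(out)
  out
}

validate_boxes <- function(boxes, what = "box") {
  need <- c("x", "y", "w", "h")
  missing <- setdiff(need, names(boxes))
  if (length(missing) > 0) {
    rlang::abort(paste0(what, " table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  bad <- which(!(boxes$w > 0 & boxes$h > 0) | is.na(boxes$w) | is.na(boxes$h))
  if (length(bad) > 0) {
    rlang::abort(paste0("invalid ", what, " at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        ": width and height must be > 0"))
  }
  invisible(boxes)
}

#' Bounding-box area
#'
#' @param boxes A box tibble (columns `x`, `y`, `w`, `h`).
#' @return Numeric vector of areas in pixels squared.
#' @export
bbox_area <- function(boxes) boxes$w * boxes$h

#' Intersection over union of box pairs
#'
#' Computes IoU — intersection area divided by union area — for pairs of
#' axis-aligned boxes under the half-open pixel convention. For integer
#' coordinates this equals the ratio of rasterised pixel counts exactly.
#' Disjoint boxes score 0; identical boxes score 1.
#'
#' @param a,b Box tibbles of equal length (or length 1, recycled).
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' bbox_iou(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10))  # 50 / 150
#' @export
bbox_iou <- function(a, b) {
  validate_boxes(a); validate_boxes(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != nrow(b) && nrow(a) != 1 && nrow(b) != 1) {
    rlang::abort("a and b must have equal row counts (or one of them a single box)")
  }
  ix <- pmax(0, pmin(a$x + a$w, b$x + b$w) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$h, b$y + b$h) - pmax(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  out <- inter / union
  rep_len(out, n)
}

#' Pairwise IoU matrix between two box sets
#'
#' @param a,b Box tibbles.
#' @return A `nrow(a)` by `nrow(b)` matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  validate_boxes(a); validate_boxes(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(matrix(numeric(0), nrow = nrow(a), ncol = nrow(b)))
  }
  ix <- pmax(0, outer(a$x + a$w, b$x + b$w, pmin) - outer(a$x, b$x, pmax))
  iy <- pmax(0, outer(a$y + a$h, b$y + b$h, pmin) - outer(a$y, b$y, pmax))
  inter <- ix * iy
  inter / (outer(a$w * a$h, b$w * b$h, `+`) - inter)
}

#' Construct a detection table
#'
#' Detections are boxes with an objectness/confidence score, a frame index
#' and the identifier of the model that produced them.
#'
#' @param x,y,w,h Box geometry (see [bbox()]).
#' @param confidence Objectness score in `[0, 1]`.
#' @param frame 0-based frame index; default 0.
#' @param source_id Model/backend identifier; default `"unknown"`.
#' @return A tibble with columns `frame`, `x`, `y`, `w`, `h`, `confidence`,
#'   `source_id`.
#' @export
detections <- function(x, y, w, h, confidence, frame = 0L,
                       source_id = "unknown") {
  out <- tibble::tibble(frame = as.integer(frame),
                        x = as.numeric(x), y = as.numeric(y),
                        w = as.numeric(w), h = as.numeric(h),
                        confidence = as.numeric(confidence),
                        source_id = as.character(source_id))
  validate_detections(out)
  out
}

validate_detections <- function(dets) {
  validate_boxes(dets, "detection")
  if (!"confidence" %in% names(dets)) {
    rlang::abort("detection table lacks a confidence column")
  }
  if (any(dets$confidence < 0 | dets$confidence > 1)) {
    rlang::abort("confidence must lie in [0, 1]")
  }
  invisible(dets)
}

#' Construct a ground-truth table
#'
#' The data set is single-class (every object is a bird), so `label` exists
#' only for file-format fidelity and defaults to `"bird"` everywhere.
#'
#' @inheritParams detections
#' @param label Class label; default `"bird"`.
#' @return A tibble with columns `frame`, `x`, `y`, `w`, `h`, `label`.
#' @export
ground_truth <- function(x, y, w, h, frame = 0L, label = "bird") {
  out <- tibble::tibble(frame = as.integer(frame),
                        x = as.numeric(x), y = as.numeric(y),
                        w = as.numeric(w), h = as.numeric(h),
                        label = as.character(label))
  validate_boxes(out, "ground-truth box")
  out
}

empty_detections <- function() {
  detections(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0),
             integer(0), character(0))
}

empty_ground_truth <- function() {
  ground_truth(numeric(0), numeric(0), numeric(0), numeric(0), integer(0),
               character(0))
}

# Greedy per-frame matcher shared by match_detections() and pr_curve().
# `dets` must already be ordered by descending confidence (ties: input
# order). Returns per-detection TP flag and matched gt row.
greedy_match <- function(dets, gts, iou_threshold) {
  n_det <- nrow(dets)
  n_gt <- nrow(gts)
  tp <- logical(n_det)
  gt_of <- rep(NA_integer_, n_det)
  if (n_det == 0 || n_gt == 0) {
    return(list(tp = tp, gt_of = gt_of))
  }
  taken <- logical(n_gt)
  det_frame <- if ("frame" %in% names(dets)) dets$frame else rep(0L, n_det)
  gt_frame <- if ("frame" %in% names(gts)) gts$frame else rep(0L, n_gt)
  iou <- iou_matrix(dets, gts)
  iou[outer(det_frame, gt_frame, `!=`)] <- -1  # never match across frames
  for (i in seq_len(n_det)) {
    cand <- iou[i, ]
    cand[taken] <- -1
    j <- which.max(cand)
    if (cand[j] >= iou_threshold) {
      tp[i] <- TRUE
      gt_of[i] <- j
      taken[j] <- TRUE
    }
  }
  list(tp = tp, gt_of = gt_of)
}

#' Match detections against ground truth
#'
#' Applies the standard VOC-style greedy assignment: detections below the
#' confidence threshold are discarded; the rest are processed in descending
#' confidence order (ties broken by input order) and each becomes a true
#' positive if it reaches `iou_threshold` with a not-yet-matched ground-truth
#' box of the same frame (taking the highest-IoU candidate), otherwise a
#' false positive. Ground-truth boxes left unmatched are false negatives.
#' Matching is per frame; multiple frames may be passed at once.
#'
#' @param dets Detection tibble (see [detections()]).
#' @param gts Ground-truth tibble (see [ground_truth()]).
#' @param iou_threshold IoU required for a match; default 0.5.
#' @param confidence_threshold Objectness gate; detections below it are
#'   dropped before matching. Default 0.25.
#' @return An object of class `sky_match`: a list with `detections` (the kept
#'   detections, in match order, with columns `det_row`, `tp`, `gt_row`),
#'   `tp`, `fp`, `fn` counts and the thresholds used.
#' @examples
#' d <- detections(0, 0, 10, 10, confidence = 0.9)
#' g <- ground_truth(0, 0, 10, 10)
#' match_detections(d, g)
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5,
                             confidence_threshold = 0.25) {
  validate_detections(dets)
  validate_boxes(gts, "ground-truth box")
  stopifnot(iou_threshold >= 0, iou_threshold <= 1,
            confidence_threshold >= 0, confidence_threshold <= 1)
  keep <- which(dets$confidence >= confidence_threshold)
  kept <- dets[keep, , drop = FALSE]
  ord <- order(-kept$confidence)  # stable: ties keep input order
  kept <- kept[ord, , drop = FALSE]
  m <- greedy_match(kept, gts, iou_threshold)
  res <- dplyr::mutate(kept, det_row = keep[ord], tp = m$tp, gt_of = m$gt_of)
  tp <- sum(m$tp)
  structure(list(
    detections = res,
    tp = tp,
    fp = nrow(kept) - tp,
    fn = nrow(gts) - tp,
    n_gt = nrow(gts),
    iou_threshold = iou_threshold,
    confidence_threshold = confidence_threshold
  ), class = "sky_match")
}

#' @export
print.sky_match <- function(x, ...) {
  cat(sprintf("<sky_match> TP %d  FP %d  FN %d  (IoU >= %.2f, conf >= %.2f)\n",
              x$tp, x$fp, x$fn, x$iou_threshold, x$confidence_threshold))
  invisible(x)
}
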