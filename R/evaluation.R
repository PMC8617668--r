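#' Precision-recall curve over a confidence sweep
#'
#' All detections (across frames) are pooled and ranked by descending
#' confidence (ties keep input order); walking down the ranking, each
#' detection is matched greedily against the not-yet-matched ground truth of
#' its own frame (best IoU at or above `iou_threshold` wins) and cumulative
#' TP/FP counts give one (recall, precision) point per detection. This is
#' the standard VOC-style curve whose exact area is the mAP.
#'
#' @param dets Detection tibble; confidences are swept, no gate applied.
#' @param gts Ground-truth tibble.
#' @param iou_threshold Match criterion; default 0.5.
#' @return A tibble of class `sky_pr` with columns `confidence`, `tp`
#'   (logical), `recall`, `precision`, and attribute `n_gt`.
#' @export
pr_curve <- function(dets, gts, iou_threshold = 0.5) {
  validate_detections(dets)
  validate_boxes(gts, "ground-truth box")
  n_gt <- nrow(gts)
  if (n_gt == 0 && nrow(dets) > 0) {
    rlang::warn("no ground-truth boxes: recall is reported as 0")
  }
  ord <- order(-dets$confidence)
  d <- dets[ord, , drop = FALSE]
  m <- greedy_match(d, gts, iou_threshold)
  ctp <- cumsum(m$tp)
  cfp <- cumsum(!m$tp)
  out <- tibble::tibble(
    confidence = d$confidence,
    tp = m$tp,
    recall = if (n_gt > 0) ctp / n_gt else rep(0, nrow(d)),
    precision = ifelse(ctp + cfp > 0, ctp / (ctp + cfp), 0))
  attr(out, "n_gt") <- n_gt
  class(out) <- c("sky_pr", class(out))
  out
}

# Monotone precision envelope: precision at recall r becomes the maximum
# precision attained at any recall >= r.
precision_envelope <- function(precision) {
  rev(cummax(rev(precision)))
}

#' VOC-style average precision (exact area under the PR curve)
#'
#' Applies the monotone precision envelope and integrates it exactly over
#' recall as a sum of rectangles between successive recall values (the VOC
#' 2010--2012 definition). With a single object class the mAP equals this
#' per-class AP.
#'
#' @param curve A [pr_curve()] result.
#' @return AP in `[0, 1]`; 0 for an empty curve.
#' @export
voc_map <- function(curve) {
  if (nrow(curve) == 0) return(0)
  env <- precision_envelope(curve$precision)
  dr <- diff(c(0, curve$recall))
  sum(dr * env)
}

#' COCO-style 101-point average precision at IoU 0.5
#'
#' Evaluates the monotone precision envelope at the 101 recall points
#' 0.00, 0.01, ..., 1.00 and averages. Recall values beyond the curve's
#' maximum score precision 0. Only the 0.5 IoU working point is offered:
#' for very small objects a stricter overlap requirement mostly measures
#' localisation jitter, not detection.
#'
#' @param curve A [pr_curve()] result.
#' @return AP50 in `[0, 1]`; 0 for an empty curve.
#' @export
coco_ap50 <- function(curve) {
  if (nrow(curve) == 0) return(0)
  env <- precision_envelope(curve$precision)
  r_grid <- seq(0, 1, by = 0.01)
  # envelope value at recall >= r: first curve point whose recall >= r
  idx <- findInterval(r_grid, curve$recall, left.open = TRUE) + 1
  p <- ifelse(idx <= length(env), env[pmin(idx, length(env))], 0)
  mean(p)
}

#' Evaluate detections against ground truth
#'
#' One-call evaluation combining the two standard reporting modes: TP/FP/FN
#' counts with precision and recall at a fixed objectness gate (default
#' 0.25), and threshold-sweep metrics (VOC mAP, COCO AP50) computed over
#' all detections regardless of the gate.
#'
#' @param dets Detection tibble.
#' @param gts Ground-truth tibble.
#' @param iou_threshold IoU match criterion; default 0.5.
#' @param confidence_threshold Objectness gate for the counts; default 0.25.
#' @return An object of class `sky_eval`; see [tidy.sky_eval()],
#'   [glance.sky_eval()] and [autoplot.sky_eval()].
#' @examples
#' g <- ground_truth(c(0, 50), c(0, 50), c(10, 10), c(10, 10))
#' d <- detections(c(0, 50), c(0, 50), c(10, 10), c(10, 10), c(0.9, 0.8))
#' evaluate_detections(d, g)
#' @export
evaluate_detections <- function(dets, gts, iou_threshold = 0.5,
                                confidence_threshold = 0.25) {
  m <- match_detections(dets, gts, iou_threshold, confidence_threshold)
  curve <- pr_curve(dets, gts, iou_threshold)
  structure(list(
    tp = m$tp, fp = m$fp, fn = m$fn,
    precision = if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0,
    recall = if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0,
    voc_map = voc_map(curve),
    coco_ap50 = coco_ap50(curve),
    curve = curve,
    n_det = nrow(dets), n_gt = nrow(gts),
    iou_threshold = iou_threshold,
    confidence_threshold = confidence_threshold
  ), class = "sky_eval")
}

#' @export
print.sky_eval <- function(x, ...) {
  cat(sprintf(paste0(
    "<sky_eval> %d detections vs %d ground truths (IoU >= %.2f)\n",
    "  counts @ conf >= %.2f: TP %d  FP %d  FN %d  P %.3f  R %.3f\n",
    "  confidence sweep:      VOC mAP %.4f  COCO AP50 %.4f\n"),
    x$n_det, x$n_gt, x$iou_threshold, x$confidence_threshold,
    x$tp, x$fp, x$fn, x$precision, x$recall, x$voc_map, x$coco_ap50))
  invisible(x)
}

#' Tidy an evaluation result
#'
#' @param x A `sky_eval` object.
#' @param ... Unused.
#' @return A tibble with one row per metric (`metric`, `value`).
#' @method tidy sky_eval
#' @export
tidy.sky_eval <- function(x, ...) {
  tibble::tibble(
    metric = c("tp", "fp", "fn", "precision", "recall", "voc_map",
               "coco_ap50"),
    value = c(x$tp, x$fp, x$fn, x$precision, x$recall, x$voc_map,
              x$coco_ap50))
}

#' One-row summary of an evaluation result
#'
#' @param x A `sky_eval` object.
#' @param ... Unused.
#' @return A one-row tibble of counts, ratios and the two AP metrics.
#' @method glance sky_eval
#' @export
glance.sky_eval <- function(x, ...) {
  tibble::tibble(n_det = x$n_det, n_gt = x$n_gt, tp = x$tp, fp = x$fp,
                 fn = x$fn, precision = x$precision, recall = x$recall,
                 voc_map = x$voc_map, coco_ap50 = x$coco_ap50)
}

#' Plot the precision-recall curve of an evaluation
#'
#' @param object A `sky_eval` object.
#' @param ... Unused.
#' @return A ggplot: raw PR points and the monotone envelope whose area is
#'   the VOC mAP.
#' @method autoplot sky_eval
#' @export
autoplot.sky_eval <- function(object, ...) {
  curve <- object$curve
  df <- tibble::tibble(recall = curve$recall,
                       precision = curve$precision,
                       envelope = precision_envelope(curve$precision))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$envelope),
                       colour = "steelblue", linewidth = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$precision),
                        alpha = 0.4, size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "recall", y = "precision",
      title = sprintf("VOC mAP %.3f | COCO AP50 %.3f",
                      object$voc_map, object$coco_ap50)) +
    ggplot2::theme_minimal()
}
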