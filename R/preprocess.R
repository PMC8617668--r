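#' Tile layout for splitting high-resolution frames
#'
#' Small birds vanish when a 4K frame is resized to a single-shot detector's
#' network resolution; splitting the frame into tiles that are each resized
#' independently keeps more pixels per bird. The default layout splits a
#' 3840x2160 frame into four 1920x1080 tiles. The grid must partition the
#' frame exactly (no overlap, no remainder).
#'
#' @param frame_w,frame_h Frame dimensions in pixels; default 3840x2160.
#' @param grid_cols,grid_rows Grid shape; default 2x2.
#' @return A list of class `tile_layout` with derived `tile_w`, `tile_h`.
#' @export
tile_layout <- function(frame_w = 3840, frame_h = 2160,
                        grid_cols = 2, grid_rows = 2) {
  stopifnot(frame_w > 0, frame_h > 0, grid_cols >= 1, grid_rows >= 1)
  if (frame_w %% grid_cols != 0 || frame_h %% grid_rows != 0) {
    rlang::abort("grid must partition the frame exactly")
  }
  structure(list(frame_w = frame_w, frame_h = frame_h,
                 grid_cols = as.integer(grid_cols),
                 grid_rows = as.integer(grid_rows),
                 tile_w = frame_w %/% grid_cols,
                 tile_h = frame_h %/% grid_rows),
            class = "tile_layout")
}

#' Split a frame into tiles
#'
#' @param frame Numeric matrix whose dimensions match the layout.
#' @param layout A [tile_layout()].
#' @return A list of tiles in row-major order; each element is a list with
#'   `tile` (matrix), `row`, `col` (0-based grid position).
#' @export
tile_frame <- function(frame, layout = tile_layout()) {
  check_frame(frame)
  if (ncol(frame) != layout$frame_w || nrow(frame) != layout$frame_h) {
    rlang::abort(sprintf("frame is %dx%d but layout expects %dx%d",
                         ncol(frame), nrow(frame),
                         layout$frame_w, layout$frame_h))
  }
  out <- list()
  for (r in seq_len(layout$grid_rows) - 1L) {
    for (c in seq_len(layout$grid_cols) - 1L) {
      rows <- r * layout$tile_h + seq_len(layout$tile_h)
      cols <- c * layout$tile_w + seq_len(layout$tile_w)
      out[[length(out) + 1L]] <-
        list(tile = frame[rows, cols, drop = FALSE], row = r, col = c)
    }
  }
  out
}

check_tile_pos <- function(row, col, layout) {
  if (row < 0 || row >= layout$grid_rows || col < 0 || col >= layout$grid_cols) {
    rlang::abort(sprintf("tile position (%d, %d) outside the %dx%d grid",
                         row, col, layout$grid_rows, layout$grid_cols))
  }
}

#' Map network-space detections on a tile back to global frame coordinates
#'
#' Each tile is resized (plain anisotropic stretch, no letterboxing) to the
#' detector's square network resolution before inference, so detections come
#' back in network coordinates. This re-projects them: box coordinates are
#' rescaled by the independent factors `tile_w / network_size` and
#' `tile_h / network_size`, then translated by the tile's global offset.
#' Confidence is untouched.
#'
#' @param dets Detection tibble in network coordinates.
#' @param row,col 0-based tile grid position.
#' @param layout A [tile_layout()].
#' @param network_size Square network input resolution; default 1024.
#' @return The detections in global frame coordinates.
#' @export
map_to_global <- function(dets, row, col, layout = tile_layout(),
                          network_size = 1024) {
  validate_detections(dets)
  check_tile_pos(row, col, layout)
  sx <- layout$tile_w / network_size
  sy <- layout$tile_h / network_size
  dplyr::mutate(dets,
                x = .data$x * sx + col * layout$tile_w,
                y = .data$y * sy + row * layout$tile_h,
                w = .data$w * sx, h = .data$h * sy)
}

#' Map global-frame detections into a tile's network coordinates
#'
#' Inverse of [map_to_global()]; round-tripping a box fully inside one tile
#' is the identity up to floating point.
#'
#' @inheritParams map_to_global
#' @param dets Detection tibble in global frame coordinates.
#' @export
map_to_network <- function(dets, row, col, layout = tile_layout(),
                           network_size = 1024) {
  validate_detections(dets)
  check_tile_pos(row, col, layout)
  sx <- network_size / layout$tile_w
  sy <- network_size / layout$tile_h
  dplyr::mutate(dets,
                x = (.data$x - col * layout$tile_w) * sx,
                y = (.data$y - row * layout$tile_h) * sy,
                w = .data$w * sx, h = .data$h * sy)
}

#' Combine per-tile detections into one frame-level set
#'
#' Concatenates detection sets already mapped to global coordinates.
#' Optionally suppresses near-duplicate boxes across tile boundaries with a
#' greedy non-maximum suppression; this is OFF by default — birds that
#' straddle a tile boundary are deliberately not handled, matching the
#' tiling scheme's stated assumption that boundary birds are rare.
#'
#' @param per_tile List of detection tibbles in global coordinates.
#' @param cross_tile_nms_iou If non-NULL, IoU above which a lower-confidence
#'   duplicate is suppressed (per frame). Default NULL (off).
#' @return One detection tibble.
#' @export
merge_tile_detections <- function(per_tile, cross_tile_nms_iou = NULL) {
  all <- dplyr::bind_rows(per_tile)
  if (nrow(all) == 0 || is.null(cross_tile_nms_iou)) return(all)
  stopifnot(cross_tile_nms_iou > 0, cross_tile_nms_iou <= 1)
  kept <- lapply(split(all, all$frame), function(d) {
    d <- d[order(-d$confidence), , drop = FALSE]
    keep <- rep(TRUE, nrow(d))
    for (i in seq_len(nrow(d))) {
      if (!keep[i]) next
      later <- which(keep & seq_len(nrow(d)) > i)
      if (length(later) == 0) next
      ious <- iou_matrix(d[i, ], d[later, , drop = FALSE])[1, ]
      keep[later[ious >= cross_tile_nms_iou]] <- FALSE
    }
    d[keep, , drop = FALSE]
  })
  dplyr::bind_rows(kept)
}

#' Stack three consecutive frames into one 3-channel input
#'
#' Packs the frames at times t-1, t and t+1 as the three channels of a
#' single input, in that order, so a single-shot detector sees short-range
#' motion cues without any explicit tracking. Raw intensities are carried
#' through unchanged.
#'
#' @param prev,cur,nxt Numeric matrices of identical shape.
#' @return A 3-d array `[h, w, 3]` with channel 2 equal to `cur`.
#' @export
temporal_stack <- function(prev, cur, nxt) {
  check_frame(prev); check_frame(cur); check_frame(nxt)
  if (!identical(dim(prev), dim(cur)) || !identical(dim(cur), dim(nxt))) {
    rlang::abort("all three frames must share the same shape")
  }
  array(c(prev, cur, nxt), dim = c(dim(cur), 3L))
}

#' Temporal stacks for a whole sequence
#'
#' An N-frame sequence yields N - 2 stacks, centred on frames 1 .. N-2
#' (0-based): the first and last frames have no complete neighbourhood and
#' are excluded.
#'
#' @param frames List of at least 3 numeric matrices.
#' @return A list of N - 2 arrays from [temporal_stack()]; each carries the
#'   attribute `center_index` (0-based index of its centre frame).
#' @export
stack_sequence <- function(frames) {
  n <- length(frames)
  if (n < 3) rlang::abort("need at least 3 frames to build temporal stacks")
  lapply(seq_len(n - 2), function(t) {
    s <- temporal_stack(frames[[t]], frames[[t + 1]], frames[[t + 2]])
    attr(s, "center_index") <- t  # 0-based: frames[[t+1]] is frame t
    s
  })
}

#' Estimate anchor boxes from ground-truth dimensions
#'
#' Runs k-means (Euclidean distance on the raw `(w, h)` pairs) on the
#' ground-truth box dimensions and returns the centroids, rounded to whole
#' pixels and sorted by area, as the detector's anchor priors. 9 anchors is
#' the standard complement for a 3-scale single-shot head (3 per scale).
#' The clustering is seeded and restarted (`nstart = 10`) so results are
#' reproducible.
#'
#' @param gt_boxes Ground-truth tibble (needs columns `w`, `h`).
#' @param k Number of anchors; default 9.
#' @param seed RNG seed for the k-means initialisation.
#' @return A tibble of class `anchor_set` with `k` rows, columns `w`, `h`,
#'   sorted ascending by `w * h`.
#' @export
estimate_anchors <- function(gt_boxes, k = 9, seed = 0) {
  validate_boxes(gt_boxes, "ground-truth box")
  if (nrow(gt_boxes) < k) {
    rlang::abort(sprintf("need at least k = %d boxes, got %d", k, nrow(gt_boxes)))
  }
  dims <- cbind(w = gt_boxes$w, h = gt_boxes$h)
  distinct <- unique(dims)
  if (nrow(distinct) <= k) {
    # degenerate: fewer distinct shapes than clusters; pad with the most
    # common shapes so exactly k anchors are still returned
    counts <- table(paste(dims[, 1], dims[, 2]))
    ord <- order(-counts)
    key <- do.call(rbind, strsplit(names(counts)[ord], " "))
    centers <- matrix(as.numeric(key), ncol = 2)
    centers <- centers[rep_len(seq_len(nrow(centers)), k), , drop = FALSE]
  } else {
    km <- local_seed(seed, stats::kmeans(dims, centers = k, nstart = 10,
                                         iter.max = 100))
    centers <- km$centers
  }
  centers <- round(centers)
  centers <- centers[order(centers[, 1] * centers[, 2], centers[, 1]), ,
                     drop = FALSE]
  out <- tibble::tibble(w = centers[, 1], h = centers[, 2])
  class(out) <- c("anchor_set", class(out))
  out
}

#' @export
format.anchor_set <- function(x, ...) {
  paste(sprintf("(%d,%d)", as.integer(x$w), as.integer(x$h)), collapse = " ")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("<anchor_set> ", format(x), "\n", sep = "")
  invisible(x)
}
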