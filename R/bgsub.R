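#' Configuration for the background-subtraction detector
#'
#' The classical detector pipeline is: absolute frame difference against a
#' running-average background model, morphological gradient (dilation minus
#' erosion) to compensate for global gain/exposure shifts, Gaussian
#' smoothing, binarisation, connected-component blob extraction, and an
#' area filter that tags components within a user-defined size range as
#' birds.
#'
#' None of the classical pipeline's scale parameters are dictated by theory;
#' they are scene-dependent knobs. Defaults: 9-pixel blur kernel (smooths
#' sensor noise while keeping few-pixel birds above threshold), square 3x3
#' structuring element, binarisation at 15 of 255 (roughly 3 sigma above the
#' blurred sensor-noise floor), and an inclusive area window of 36--5000
#' px^2 (36 px^2 is the smallest bird size category that occurs in this
#' kind of footage; the upper bound rejects cloud banks).
#'
#' @param blur_kernel_size Odd Gaussian kernel size in pixels; default 9.
#' @param min_area,max_area Inclusive blob-area window in px^2.
#' @param binarize_threshold Intensity (0--255 scale) above which a blurred
#'   foreground pixel counts as object; default 15.
#' @param morph_kernel_size Odd square structuring-element size; default 3.
#' @return A list of class `bgsub_config`.
#' @export
bgsub_config <- function(blur_kernel_size = 9, min_area = 36,
                         max_area = 5000, binarize_threshold = 15,
                         morph_kernel_size = 3) {
  odd_or_abort(blur_kernel_size, "blur_kernel_size")
  odd_or_abort(morph_kernel_size, "morph_kernel_size")
  stopifnot(min_area > 0, min_area < max_area, binarize_threshold > 0)
  structure(list(blur_kernel_size = as.integer(blur_kernel_size),
                 min_area = min_area, max_area = max_area,
                 binarize_threshold = binarize_threshold,
                 morph_kernel_size = as.integer(morph_kernel_size)),
            class = "bgsub_config")
}

#' Create a running-average background model
#'
#' The model keeps a per-pixel intensity estimate `B` of the empty scene.
#' After each frame it is updated as `B <- (1 - a) * B + a * I` with an
#' effective rate `a = max(alpha, 1/n)` after `n` frames: during warm-up
#' the model is the cumulative mean of all frames seen (so anything present
#' only in the first frames — including birds — decays like `1/n` instead
#' of lingering as a ghost), and it then settles into an exponential
#' running average with rate `alpha` that tracks slow illumination changes
#' while transient objects leave only a geometrically decaying trace.
#'
#' @param learning_rate Update weight `alpha` in `(0, 1]`; default 0.05.
#' @return A list of class `bg_model` with fields `background` (NULL until
#'   the first frame), `learning_rate`, `n_seen` and `initialized`.
#' @export
bg_model <- function(learning_rate = 0.05) {
  stopifnot(learning_rate > 0, learning_rate <= 1)
  structure(list(background = NULL, learning_rate = learning_rate,
                 n_seen = 0L, initialized = FALSE),
            class = "bg_model")
}

#' Subtract the background model from a frame and update it
#'
#' Returns the absolute difference `|I - B|` and the model updated by the
#' running average. On the very first frame the model is initialised to the
#' frame itself and the difference is all zero.
#'
#' @param model A [bg_model()].
#' @param frame Numeric matrix (grayscale, rows = y).
#' @return A list with `model` (updated) and `diff` (matrix, same shape).
#' @export
bg_subtract <- function(model, frame) {
  check_frame(frame)
  if (!inherits(model, "bg_model")) rlang::abort("model must be a bg_model")
  if (!model$initialized) {
    model$background <- frame
    model$initialized <- TRUE
    model$n_seen <- 1L
    return(list(model = model, diff = matrix(0, nrow(frame), ncol(frame))))
  }
  if (!identical(dim(model$background), dim(frame))) {
    rlang::abort("frame shape does not match the initialized background model")
  }
  d <- abs(frame - model$background)
  model$n_seen <- model$n_seen + 1L
  a <- max(model$learning_rate, 1 / model$n_seen)
  model$background <- (1 - a) * model$background + a * frame
  list(model = model, diff = d)
}

#' Morphological gradient of a grayscale image
#'
#' Dilation minus erosion with a square structuring element. For the
#' classical detector this acts as a cheap gain/exposure compensation: a
#' global intensity offset in the difference image has zero gradient, while
#' compact foreground blobs keep strong local contrast.
#'
#' @param img Numeric matrix.
#' @param kernel_size Odd structuring-element side; default 3.
#' @return Matrix of the same shape, everywhere `>= 0`.
#' @export
morph_gradient <- function(img, kernel_size = 3) {
  check_frame(img)
  k <- odd_or_abort(kernel_size, "kernel_size")
  brush <- EBImage::makeBrush(k, shape = "box")
  # EBImage grayscale morphology expects intensities in [0, 1]; map the
  # image there and back so arbitrary intensity scales are handled
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(matrix(0, nrow(img), ncol(img)))
  u <- (img - lo) / (hi - lo)
  (EBImage::dilate(u, brush) - EBImage::erode(u, brush)) * (hi - lo)
}

# Gaussian kernel for a given odd size; sigma follows the common
# size-derived rule sigma = 0.3 * ((k - 1)/2 - 1) + 0.8 used by OpenCV
# when only a kernel size is given, so "kernel of size 9" is reproducible.
gaussian_kernel_1d <- function(kernel_size) {
  k <- odd_or_abort(kernel_size, "kernel_size")
  sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  r <- (k - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable 1-D convolution along rows (margin = 1) or columns (margin = 2)
# with replicate edge padding.
conv_sep <- function(img, kernel, margin) {
  r <- (length(kernel) - 1) / 2
  n <- dim(img)[margin]
  idx <- pmin(pmax(seq(1 - r, n + r), 1), n)
  out <- 0
  if (margin == 1L) {
    pad <- img[idx, , drop = FALSE]
    for (o in seq_along(kernel)) {
      out <- out + kernel[o] * pad[o:(n + o - 1), , drop = FALSE]
    }
  } else {
    pad <- img[, idx, drop = FALSE]
    for (o in seq_along(kernel)) {
      out <- out + kernel[o] * pad[, o:(n + o - 1), drop = FALSE]
    }
  }
  out
}

#' Gaussian blur with a given kernel size
#'
#' Separable Gaussian smoothing with replicate edge padding, so a constant
#' image is reproduced exactly and total intensity of interior features is
#' preserved (the kernel is normalised).
#'
#' @param img Numeric matrix.
#' @param kernel_size Odd kernel size; default 9.
#' @return Matrix of the same shape.
#' @export
gaussian_blur <- function(img, kernel_size = 9) {
  check_frame(img)
  g <- gaussian_kernel_1d(kernel_size)
  conv_sep(conv_sep(img, g, 1L), g, 2L)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a union-find over the
# label adjacency graph.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(edges) == 0) return(lab)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  relab <- c(0L, as.integer(memb))
  matrix(relab[lab + 1L], nr, nc)
}

#' Detect blobs in a blurred foreground map
#'
#' Binarises the image at `config$binarize_threshold` (inclusive), extracts
#' 8-connected components, and summarises each as a blob with centroid and
#' equivalent-circle radius `sqrt(area / pi)`. Centroids are reported as the
#' mean of the member pixels' 0-based indices.
#'
#' @param img Numeric matrix (typically the blurred difference image).
#' @param config A [bgsub_config()].
#' @return A tibble with columns `center_x`, `center_y`, `radius`,
#'   `area_px` (pixel count); zero rows for a blank image.
#' @export
detect_blobs <- function(img, config = bgsub_config()) {
  check_frame(img)
  mask <- img >= config$binarize_threshold
  if (!any(mask)) {
    return(tibble::tibble(center_x = numeric(0), center_y = numeric(0),
                          radius = numeric(0), area_px = numeric(0)))
  }
  lab <- label_components8(mask)
  px <- which(lab > 0, arr.ind = TRUE)
  id <- lab[lab > 0]
  area <- tabulate(id)
  keep <- which(area > 0)
  cx <- rowsum(as.numeric(px[, 2] - 1), id)[, 1] / area[keep]
  cy <- rowsum(as.numeric(px[, 1] - 1), id)[, 1] / area[keep]
  tibble::tibble(center_x = unname(cx), center_y = unname(cy),
                 radius = sqrt(area[keep] / pi),
                 area_px = as.numeric(area[keep]))
}

#' Convert area-filtered blobs to detections
#'
#' Blobs whose equivalent-circle area `pi * radius^2` lies inside the
#' inclusive `[min_area, max_area]` window become detections; the rest are
#' discarded. Each detection's box is the blob's bounding square of side
#' `2 * radius` centred on the centroid, clipped to the frame, and its
#' confidence is fixed at 1.0 — the classical detector has no objectness
#' notion, and the fixed score lets its output flow through evaluation code
#' that applies an objectness gate.
#'
#' @param blobs Tibble from [detect_blobs()].
#' @param config A [bgsub_config()].
#' @param frame_w,frame_h Frame dimensions for clipping.
#' @param frame Frame index stamped on the detections.
#' @return A detection tibble (see [detections()]), `source_id = "bgsub"`.
#' @export
blobs_to_boxes <- function(blobs, config = bgsub_config(),
                           frame_w = Inf, frame_h = Inf, frame = 0L) {
  area <- pi * blobs$radius^2
  keep <- area >= config$min_area & area <= config$max_area
  b <- blobs[keep, , drop = FALSE]
  if (nrow(b) == 0) return(empty_detections())
  x0 <- pmax(0, b$center_x - b$radius)
  y0 <- pmax(0, b$center_y - b$radius)
  x1 <- pmin(frame_w, b$center_x + b$radius)
  y1 <- pmin(frame_h, b$center_y + b$radius)
  detections(x = x0, y = y0, w = x1 - x0, h = y1 - y0,
             confidence = 1, frame = frame, source_id = "bgsub")
}

#' Run the classical detector on one frame
#'
#' Composes the pipeline stages in order: background subtraction,
#' morphological gradient, Gaussian blur, blob detection, area filter.
#' Intermediate images are returned for inspection.
#'
#' @param model A [bg_model()]; pass the updated model to the next frame.
#' @param frame Numeric matrix.
#' @param config A [bgsub_config()].
#' @param frame_index Frame index stamped on detections.
#' @return List with `model` (updated), `detections` (tibble) and `stages`
#'   (list of intermediate matrices: `diff`, `gradient`, `blurred`).
#' @export
detect_frame <- function(model, frame, config = bgsub_config(),
                         frame_index = 0L) {
  s <- bg_subtract(model, frame)
  grad <- morph_gradient(s$diff, config$morph_kernel_size)
  blur <- gaussian_blur(grad, config$blur_kernel_size)
  blobs <- detect_blobs(blur, config)
  dets <- blobs_to_boxes(blobs, config, frame_w = ncol(frame),
                         frame_h = nrow(frame), frame = frame_index)
  list(model = s$model, detections = dets,
       stages = list(diff = s$diff, gradient = grad, blurred = blur))
}

#' Run the classical detector over a frame sequence
#'
#' Feeds frames through [detect_frame()] in order, threading the background
#' model. The first `warmup` frames still update the model but their
#' detections are discarded (the model needs a few frames to settle after
#' its initialisation to the first frame).
#'
#' @param frames List of numeric matrices, all the same shape.
#' @param config A [bgsub_config()].
#' @param learning_rate Background-model update weight; default 0.05.
#' @param warmup Number of leading frames whose detections are dropped;
#'   default 5 (by then a first-frame transient has decayed to intensity/5,
#'   under the default binarisation threshold for typical bird contrasts).
#' @return A detection tibble over all frames (frame indices are 0-based
#'   positions in `frames`).
#' @export
bgsub_detect <- function(frames, config = bgsub_config(),
                         learning_rate = 0.05, warmup = 5L) {
  stopifnot(length(frames) >= 1, warmup >= 0)
  model <- bg_model(learning_rate)
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    r <- detect_frame(model, frames[[i]], config, frame_index = i - 1L)
    model <- r$model
    out[[i]] <- if (i - 1L < warmup) empty_detections() else r$detections
  }
  dplyr::bind_rows(out)
}
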