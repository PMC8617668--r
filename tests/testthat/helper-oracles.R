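# Independent oracles used across the suite.

# IoU by literal rasterization: paint both boxes onto a pixel grid and
# count. Only valid for non-negative integer coordinates.
rasterized_iou <- function(a, b) {
  W <- max(a$x + a$w, b$x + b$w)
  H <- max(a$y + a$h, b$y + b$h)
  ma <- matrix(FALSE, H, W)
  mb <- matrix(FALSE, H, W)
  ma[(a$y + 1):(a$y + a$h), (a$x + 1):(a$x + a$w)] <- TRUE
  mb[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w)] <- TRUE
  inter <- sum(ma & mb)
  inter / sum(ma | mb)
}

# Exact area under the monotone precision envelope, computed from first
# principles: the envelope f(r) = max{precision_j : recall_j >= r} is
# piecewise constant between consecutive distinct recall values, so the
# integral is a finite sum of rectangles evaluated at segment midpoints.
ap_envelope_oracle <- function(recall, precision) {
  if (length(recall) == 0) return(0)
  bp <- sort(unique(c(0, recall)))
  total <- 0
  for (k in seq_len(length(bp) - 1)) {
    mid <- (bp[k] + bp[k + 1]) / 2
    cand <- precision[recall >= mid]
    total <- total + (bp[k + 1] - bp[k]) * (if (length(cand)) max(cand) else 0)
  }
  total
}

# Random integer box tibble for fuzz tests.
random_boxes <- function(n, max_xy = 40, max_wh = 15) {
  bbox(x = sample.int(max_xy, n, replace = TRUE) - 1,
       y = sample.int(max_xy, n, replace = TRUE) - 1,
       w = sample.int(max_wh, n, replace = TRUE),
       h = sample.int(max_wh, n, replace = TRUE))
}

# Hand-built scene: one dark elliptical bird of box size bw x bh moving
# left-to-right over a flat sky; returns frames plus true integer boxes.
# Used where full control over the trajectory is wanted, independent of
# the package generator.
make_moving_bird_frames <- function(n_frames = 12, w = 200, h = 120,
                                    bw = 12, bh = 12, step = 6,
                                    sky = 170, delta = 60, noise_sd = 0,
                                    seed = 42) {
  set.seed(seed)
  frames <- vector("list", n_frames)
  gt <- vector("list", n_frames)
  for (t in seq_len(n_frames) - 1L) {
    f <- matrix(sky, h, w)
    if (noise_sd > 0) f <- f + matrix(rnorm(h * w, sd = noise_sd), h, w)
    x <- 20 + step * t
    y <- round(h / 2 - bh / 2)
    cx <- x + bw / 2; cy <- y + bh / 2
    for (r in (y + 1):(y + bh)) {
      for (c in (x + 1):(x + bw)) {
        if (((c - 0.5 - cx) / (bw / 2))^2 + ((r - 0.5 - cy) / (bh / 2))^2 <= 1) {
          f[r, c] <- f[r, c] - delta
        }
      }
    }
    frames[[t + 1L]] <- f
    gt[[t + 1L]] <- ground_truth(x, y, bw, bh, frame = t)
  }
  list(frames = frames, gt = dplyr::bind_rows(gt))
}
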