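test_that("the default layout yields four 1920x1080 tiles that reassemble", {
  lay <- tile_layout()
  expect_equal(c(lay$tile_w, lay$tile_h), c(1920, 1080))
  frame <- matrix(seq_len(2160 * 3840) %% 251, 2160, 3840)
  tiles <- tile_frame(frame, lay)
  expect_length(tiles, 4)
  expect_equal(dim(tiles[[1]]$tile), c(1080, 1920))
  rebuilt <- matrix(0, 2160, 3840)
  for (t in tiles) {
    rows <- t$row * lay$tile_h + seq_len(lay$tile_h)
    cols <- t$col * lay$tile_w + seq_len(lay$tile_w)
    rebuilt[rows, cols] <- t$tile
  }
  expect_identical(rebuilt, frame)
})

test_that("a 2x2 frame tiles into four single pixels in row-major order", {
  frame <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] by row
  tiles <- tile_frame(frame, tile_layout(2, 2, 2, 2))
  expect_equal(vapply(tiles, function(t) t$tile[1, 1], numeric(1)),
               c(1, 2, 3, 4))
  expect_equal(vapply(tiles, function(t) t$row, numeric(1)), c(0, 0, 1, 1))
  expect_equal(vapply(tiles, function(t) t$col, numeric(1)), c(0, 1, 0, 1))
})

test_that("tiling rejects mismatched frames and non-partitioning grids", {
  expect_error(tile_frame(matrix(0, 100, 100), tile_layout()), "layout expects")
  expect_error(tile_layout(100, 100, 3, 2), "partition")
})

test_that("network-to-global mapping matches the scale-and-translate rule", {
  lay <- tile_layout()
  d0 <- detections(0, 0, 64, 64, 0.7)
  g0 <- map_to_global(d0, 0, 0, lay, 1024)
  expect_equal(c(g0$x, g0$y), c(0, 0))

  d <- detections(512, 512, 64, 64, 0.9)
  g <- map_to_global(d, row = 0, col = 1, lay, 1024)
  expect_equal(g$x, 1920 + 512 * 1920 / 1024)  # 2880
  expect_equal(g$y, 512 * 1080 / 1024)         # 540
  expect_equal(g$w, 120)
  expect_equal(g$h, 67.5)
  expect_equal(g$confidence, 0.9)
  expect_error(map_to_global(d, 2, 0, lay), "outside")
})

test_that("tile coordinate mapping round-trips interior boxes", {
  set.seed(3)
  lay <- tile_layout()
  for (i in 1:20) {
    row <- sample(0:1, 1); col <- sample(0:1, 1)
    d <- detections(x = runif(1, 0, 900) + col * 1920,
                    y = runif(1, 0, 500) + row * 1080,
                    w = runif(1, 5, 100), h = runif(1, 5, 100),
                    confidence = runif(1))
    back <- map_to_global(map_to_network(d, row, col, lay), row, col, lay)
    expect_equal(back$x, d$x, tolerance = 1e-9)
    expect_equal(back$y, d$y, tolerance = 1e-9)
    expect_equal(back$w, d$w, tolerance = 1e-9)
  }
})

test_that("tile merging concatenates and optionally deduplicates", {
  expect_equal(nrow(merge_tile_detections(list(empty_detections(),
                                               empty_detections()))), 0)
  a <- detections(0, 0, 10, 10, 0.9)
  b <- detections(500, 500, 10, 10, 0.8)
  expect_equal(nrow(merge_tile_detections(list(a, b))), 2)

  # near-duplicates across a boundary survive by default (off) ...
  dup <- detections(c(1915, 1916), c(100, 100), c(20, 20), c(20, 20),
                    c(0.9, 0.7))
  expect_equal(nrow(merge_tile_detections(list(dup))), 2)
  # ... and collapse to the higher-confidence one with NMS enabled
  kept <- merge_tile_detections(list(dup), cross_tile_nms_iou = 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)
})

test_that("temporal stacks order channels (t-1, t, t+1)", {
  a <- matrix(1, 4, 5); b <- matrix(2, 4, 5); c <- matrix(3, 4, 5)
  s <- temporal_stack(a, b, c)
  expect_equal(dim(s), c(4, 5, 3))
  expect_identical(s[, , 2], b)
  expect_identical(s[, , 1], a)
  expect_error(temporal_stack(a, b, matrix(3, 5, 5)), "shape")

  same <- temporal_stack(b, b, b)
  for (k in 1:3) expect_identical(same[, , k], b)
})

test_that("stacking a sequence drops the first and last frames", {
  frames <- lapply(1:10, function(i) matrix(i, 3, 3))
  stacks <- stack_sequence(frames)
  expect_length(stacks, 8)
  for (k in seq_along(stacks)) {
    expect_identical(stacks[[k]][, , 2], frames[[k + 1]])
    expect_equal(attr(stacks[[k]], "center_index"), k)
  }
  expect_length(stack_sequence(frames[1:3]), 1)
  expect_error(stack_sequence(frames[1:2]), "at least 3")
})

test_that("anchor estimation recovers well-separated planted clusters", {
  set.seed(9)
  centers <- cbind(w = c(5, 9, 14, 20, 28, 38, 50, 70, 95),
                   h = c(6, 10, 13, 22, 26, 40, 48, 75, 100))
  gt <- do.call(dplyr::bind_rows, lapply(seq_len(9), function(i) {
    ground_truth(x = 0, y = 0,
                 w = centers[i, 1] + runif(10, -0.3, 0.3),
                 h = centers[i, 2] + runif(10, -0.3, 0.3))
  }))
  anc <- estimate_anchors(gt, k = 9, seed = 4)
  expect_equal(nrow(anc), 9)
  expect_true(all(diff(anc$w * anc$h) >= 0))
  expect_true(all(abs(anc$w - centers[, 1]) <= 1))
  expect_true(all(abs(anc$h - centers[, 2]) <= 1))
})

test_that("anchor estimation is deterministic and handles degeneracy", {
  set.seed(10)
  g <- random_boxes(60)
  gt <- ground_truth(g$x, g$y, g$w, g$h)
  expect_identical(estimate_anchors(gt, seed = 1), estimate_anchors(gt, seed = 1))

  same <- ground_truth(rep(0, 20), rep(0, 20), rep(8, 20), rep(6, 20))
  anc <- estimate_anchors(same)
  expect_equal(nrow(anc), 9)
  expect_true(all(anc$w == 8 & anc$h == 6))

  expect_error(estimate_anchors(gt[1:5, ]), "at least")
})

test_that("anchors print in the darknet (w,h) text form", {
  gt <- ground_truth(rep(0, 20), rep(0, 20), w = rep(1:10, 2), h = rep(1:10, 2))
  anc <- estimate_anchors(gt, seed = 0)
  expect_match(format(anc), "^\\(\\d+,\\d+\\)( \\(\\d+,\\d+\\)){8}$")
})
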