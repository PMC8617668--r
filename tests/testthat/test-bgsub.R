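test_that("background subtraction initialises on the first frame", {
  m <- bg_model(0.05)
  f <- matrix(runif(50, 0, 255), 5, 10)
  r <- bg_subtract(m, f)
  expect_equal(r$diff, matrix(0, 5, 10))
  expect_true(r$model$initialized)
  expect_equal(r$model$background, f)
})

test_that("a constant frame stream keeps the difference at zero", {
  m <- bg_model(0.1)
  f <- matrix(120, 8, 8)
  for (i in 1:5) {
    r <- bg_subtract(m, f)
    m <- r$model
    expect_equal(r$diff, matrix(0, 8, 8))
  }
})

test_that("difference against a black background isolates a bright pixel", {
  m <- bg_model(0.05)
  m <- bg_subtract(m, matrix(0, 6, 6))$model  # B initialised all-zero
  f <- matrix(0, 6, 6); f[3, 4] <- 255
  d <- bg_subtract(m, f)$diff
  expect_equal(sum(d != 0), 1)
  expect_equal(d[3, 4], 255)
})

test_that("frame shape mismatch against an initialised model errors", {
  m <- bg_subtract(bg_model(), matrix(0, 4, 4))$model
  expect_error(bg_subtract(m, matrix(0, 5, 5)), "shape")
})

test_that("transients decay like 1/n during the cumulative warm-up", {
  m <- bg_model(0.05)
  spot <- matrix(0, 4, 4); spot[2, 2] <- 100
  m <- bg_subtract(m, spot)$model       # transient in first frame only
  for (i in 1:4) m <- bg_subtract(m, matrix(0, 4, 4))$model
  expect_equal(m$background[2, 2], 100 / 5, tolerance = 1e-12)
})

test_that("morphological gradient matches hand-computed dilation - erosion", {
  expect_equal(morph_gradient(matrix(7, 6, 6)), matrix(0, 6, 6))
  img <- matrix(0, 5, 5); img[3, 3] <- 40
  g <- morph_gradient(img, 3)
  want <- matrix(0, 5, 5); want[2:4, 2:4] <- 40
  expect_equal(g, want)
  expect_error(morph_gradient(img, 4), "odd")
  set.seed(1)
  r <- matrix(runif(100, 0, 255), 10, 10)
  expect_true(all(morph_gradient(r) >= 0))
})

test_that("Gaussian blur is normalised, symmetric and shape-preserving", {
  expect_equal(gaussian_blur(matrix(55, 20, 20)), matrix(55, 20, 20))
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1000
  b <- gaussian_blur(imp, 9)
  expect_equal(dim(b), c(21, 21))
  expect_equal(sum(b), 1000, tolerance = 0.01)      # kernel sums to 1
  expect_equal(b, b[21:1, ], tolerance = 1e-12)     # symmetric response
  expect_equal(b, t(b), tolerance = 1e-12)
  expect_error(gaussian_blur(imp, 8), "odd")
})

test_that("blob detection recovers centroid, radius and count", {
  cfg <- bgsub_config()
  expect_equal(nrow(detect_blobs(matrix(0, 50, 50), cfg)), 0)

  img <- matrix(0, 200, 200)
  img[101:110, 101:110] <- 200  # 10x10 square at 0-based (100, 100)
  b <- detect_blobs(img, cfg)
  expect_equal(nrow(b), 1)
  expect_equal(b$center_x, 104.5)
  expect_equal(b$center_y, 104.5)
  expect_equal(b$radius, sqrt(100 / pi))

  img[41:45, 41:45] <- 200      # second, well-separated square
  expect_equal(nrow(detect_blobs(img, cfg)), 2)
})

test_that("blob extraction is 8-connected", {
  img <- matrix(0, 10, 10)
  img[3, 3] <- 200; img[4, 4] <- 200  # touch only diagonally
  expect_equal(nrow(detect_blobs(img, bgsub_config())), 1)
})

test_that("area filter bounds are inclusive and small blobs are dropped", {
  cfg <- bgsub_config(min_area = 36, max_area = 5000)
  tiny <- tibble::tibble(center_x = 10, center_y = 10, radius = 1,
                         area_px = pi)
  expect_equal(nrow(blobs_to_boxes(tiny, cfg)), 0)  # pi * 1^2 < 36

  at_min <- tibble::tibble(center_x = 20, center_y = 20,
                           radius = sqrt(36 / pi), area_px = 36)
  expect_equal(nrow(blobs_to_boxes(at_min, cfg)), 1)

  empty <- detect_blobs(matrix(0, 5, 5), cfg)
  expect_equal(nrow(blobs_to_boxes(empty, cfg)), 0)
})

test_that("the full pipeline localises a single moving bird", {
  # the running-average model keeps a decaying trail of past positions; by
  # frame 10 the trail is below the binarisation threshold and the blob
  # centroid tracks the bird tightly
  scn <- make_moving_bird_frames(n_frames = 20, bw = 12, bh = 12,
                                 step = 6, noise_sd = 1)
  dets <- bgsub_detect(scn$frames, warmup = 10)
  for (t in 10:19) {
    d <- dets[dets$frame == t, ]
    expect_equal(nrow(d), 1)
    g <- scn$gt[scn$gt$frame == t, ]
    dist <- sqrt((d$x + d$w / 2 - g$x - g$w / 2)^2 +
                 (d$y + d$h / 2 - g$y - g$h / 2)^2)
    expect_lt(dist, 3)
  }
})

test_that("an empty static scene yields no detections after warm-up", {
  set.seed(5)
  frames <- lapply(1:10, function(i) {
    matrix(170 + rnorm(120 * 200, sd = 2), 120, 200)
  })
  dets <- bgsub_detect(frames, warmup = 3)
  expect_equal(nrow(dets), 0)
})

test_that("the detector is deterministic for identical frames and config", {
  scn <- make_moving_bird_frames(noise_sd = 2)
  expect_identical(bgsub_detect(scn$frames), bgsub_detect(scn$frames))
})

test_that("intermediate stage images are retrievable and feed in order", {
  scn <- make_moving_bird_frames(n_frames = 3)
  model <- bg_model()
  model <- detect_frame(model, scn$frames[[1]])$model
  r <- detect_frame(model, scn$frames[[2]], frame_index = 1L)
  expect_named(r$stages, c("diff", "gradient", "blurred"))
  expect_equal(r$stages$gradient,
               morph_gradient(r$stages$diff, bgsub_config()$morph_kernel_size))
  expect_equal(r$stages$blurred,
               gaussian_blur(r$stages$gradient, bgsub_config()$blur_kernel_size))
})
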