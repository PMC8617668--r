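small_cfg <- function(...) {
  args <- utils::modifyList(
    list(frame_w = 320, frame_h = 180, n_frames = 8, n_birds = 5, seed = 41),
    list(...))
  do.call(sky_scene_config, args)
}

test_that("a scene with no birds has frames but no ground truth", {
  s <- generate_sequence(small_cfg(n_birds = 0))
  expect_length(s$frames, 8)
  expect_equal(nrow(s$gt), 0)
})

test_that("the same seed reproduces the sequence bit for bit", {
  a <- generate_sequence(small_cfg())
  b <- generate_sequence(small_cfg())
  expect_identical(a$frames, b$frames)
  expect_identical(a$gt, b$gt)
  c <- generate_sequence(small_cfg(seed = 42))
  expect_false(identical(a$frames[[1]], c$frames[[1]]))
})

test_that("ground-truth box areas respect the configured range exactly", {
  s <- generate_sequence(small_cfg(n_frames = 20, n_birds = 10))
  areas <- bbox_area(s$gt)
  expect_true(all(areas >= 36 & areas <= 2000))
  sk <- generate_sequence(sky_preset("skagen", frame_w = 320, frame_h = 180,
                                     n_frames = 10, seed = 5))
  expect_true(all(bbox_area(sk$gt) <= 500))
})

test_that("ground-truth boxes tightly contain the darkened pixels", {
  cfg <- small_cfg(noise_sigma = 0, n_frames = 6)
  s <- generate_sequence(cfg)
  base <- generate_sequence(small_cfg(noise_sigma = 0, n_frames = 6,
                                      n_birds = 0))
  for (t in 0:5) {
    dark <- which(s$frames[[t + 1]] < base$frames[[t + 1]] - 1,
                  arr.ind = TRUE)
    px <- tibble::tibble(x = dark[, 2] - 1, y = dark[, 1] - 1)
    boxes <- s$gt[s$gt$frame == t, ]
    # every darkened pixel inside some box
    inside <- vapply(seq_len(nrow(px)), function(i) {
      any(px$x[i] >= boxes$x & px$x[i] < boxes$x + boxes$w &
          px$y[i] >= boxes$y & px$y[i] < boxes$y + boxes$h)
    }, logical(1))
    expect_true(all(inside))
    # tightness: every box edge touches a darkened pixel
    for (b in seq_len(nrow(boxes))) {
      in_b <- px$x >= boxes$x[b] & px$x < boxes$x[b] + boxes$w[b] &
        px$y >= boxes$y[b] & px$y < boxes$y[b] + boxes$h[b]
      if (!any(in_b)) next  # box fully occluded by an overlapping bird
      expect_equal(min(px$x[in_b]), boxes$x[b])
      expect_equal(max(px$x[in_b]), boxes$x[b] + boxes$w[b] - 1)
      expect_equal(min(px$y[in_b]), boxes$y[b])
      expect_equal(max(px$y[in_b]), boxes$y[b] + boxes$h[b] - 1)
    }
  }
})

test_that("dynamic backgrounds move more energy frame to frame than static", {
  st <- generate_sequence(small_cfg(n_birds = 0, background_mode = "static"))
  dy <- generate_sequence(small_cfg(n_birds = 0, background_mode = "dynamic"))
  energy <- function(frames) {
    mean(vapply(2:length(frames), function(i) {
      mean((frames[[i]] - frames[[i - 1]])^2)
    }, numeric(1)))
  }
  expect_gt(energy(dy$frames), energy(st$frames))
})

test_that("static and dynamic scenes share identical bird ground truth", {
  st <- generate_sequence(small_cfg(background_mode = "static"))
  dy <- generate_sequence(small_cfg(background_mode = "dynamic"))
  expect_identical(st$gt, dy$gt)
})

test_that("the size mixture hits its sub-cutoff fraction on a large sample", {
  s <- generate_sequence(sky_scene_config(frame_w = 640, frame_h = 360,
                                          n_frames = 30, n_birds = 20,
                                          seed = 44))
  frac <- mean(bbox_area(s$gt) < 500)
  expect_lt(abs(frac - 1000 / 2400), 0.08)  # 600 boxes, ~110 size draws
})

test_that("a noise-free simulated detector reproduces the ground truth", {
  s <- generate_sequence(small_cfg())
  d <- simulate_detector(s$gt, sim_detector_config(miss_rate = 0,
                                                   fp_rate = 0,
                                                   jitter_sigma = 0),
                         frame_w = 320, frame_h = 180)
  expect_equal(nrow(d), nrow(s$gt))
  expect_equal(d$x, s$gt$x)
  expect_equal(d$w, s$gt$w)
  expect_true(all(d$confidence >= 0.5 & d$confidence <= 1))
})

test_that("miss_rate = 1 silences the detector; counts follow the binomial", {
  s <- generate_sequence(small_cfg(n_frames = 25, n_birds = 8))
  d1 <- simulate_detector(s$gt, sim_detector_config(miss_rate = 1, fp_rate = 0),
                          320, 180)
  expect_equal(nrow(d1), 0)

  n <- nrow(s$gt)
  d <- simulate_detector(s$gt, sim_detector_config(miss_rate = 0.4,
                                                   fp_rate = 0, seed = 8),
                         320, 180)
  sd3 <- 3 * sqrt(n * 0.4 * 0.6)
  expect_lt(abs(nrow(d) - 0.6 * n), sd3)
})

test_that("the simulated detector is deterministic per seed", {
  s <- generate_sequence(small_cfg())
  cfg <- sim_detector_config(miss_rate = 0.3, fp_rate = 1, seed = 9)
  expect_identical(simulate_detector(s$gt, cfg, 320, 180),
                   simulate_detector(s$gt, cfg, 320, 180))
})

test_that("oversized birds are rejected at config time", {
  expect_error(sky_scene_config(frame_w = 40, frame_h = 40,
                                bird_area_range = c(36, 2000)),
               "too large")
})
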