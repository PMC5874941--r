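test_that("channel isolation keeps the own colour and suppresses background", {
  px <- array(0L, c(2, 2, 3))
  px[1, 1, ] <- c(255L, 0L, 0L)      # pure red
  px[1, 2, ] <- c(255L, 255L, 255L)  # white background
  px[2, 1, ] <- c(200L, 50L, 0L)     # reddish
  px[2, 2, ] <- c(30L, 160L, 40L)    # green dot colour
  fr <- new_frame(px)

  red <- channel_isolate(fr, "red")
  green <- channel_isolate(fr, "green")
  expect_equal(red[1, 1], 255L)
  expect_equal(red[1, 2], 0L)       # white suppressed
  expect_equal(green[1, 2], 0L)
  expect_equal(green[2, 1], 0L)     # clipped at zero for the opposing colour
  expect_equal(red[2, 1], 150L)
  expect_equal(green[2, 2], 130L)
})

test_that("median filter removes specks, keeps constants, rejects even windows", {
  const <- matrix(17L, 8, 8)
  expect_equal(median_denoise(const, 5), const)

  speck <- matrix(0L, 11, 11)
  speck[6, 6] <- 255L
  expect_equal(median_denoise(speck, 5), matrix(0L, 11, 11))

  expect_error(median_denoise(const, 4), "odd")
})

test_that("median filter matches the brute-force oracle on random images", {
  set.seed(101)
  # 8-bit path at several sizes and windows
  for (case in 1:12) {
    h <- sample(3:32, 1)
    w <- sample(3:32, 1)
    win <- sample(c(3, 5, 7), 1)
    img <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
    expect_equal(median_denoise(img, win), median_oracle(img, win),
                 info = sprintf("u8 %dx%d win %d", h, w, win))
  }
  # general numeric path (values outside 0..255, non-integers)
  for (case in 1:6) {
    h <- sample(3:20, 1)
    w <- sample(3:20, 1)
    img <- matrix(rnorm(h * w, sd = 100), h, w)
    expect_equal(median_denoise(img, 3), median_oracle(img, 3),
                 info = sprintf("dbl %dx%d", h, w))
  }
  # the 9x9 window-3 case as a plain spot check
  img <- matrix(sample(0:50, 81, replace = TRUE), 9, 9)
  expect_equal(median_denoise(img, 3), median_oracle(img, 3))
})

test_that("range-relative threshold behaves per definition and is monotone", {
  two <- matrix(c(0, 200, 0, 200), 2, 2)
  expect_equal(threshold_mask(two, 0.5), two == 200, ignore_attr = TRUE)

  const <- matrix(5, 3, 3)
  m <- threshold_mask(const, 0.5)
  expect_false(any(m))
  expect_true(attr(m, "degenerate"))

  ramp <- matrix(0:255, 16, 16)
  expect_equal(threshold_mask(ramp, 0.5), ramp >= 127.5, ignore_attr = TRUE)

  # monotonicity: raising the fraction never adds mask pixels
  set.seed(11)
  img <- matrix(runif(400, 0, 255), 20, 20)
  fracs <- c(0.2, 0.4, 0.6, 0.8)
  masks <- lapply(fracs, function(f) threshold_mask(img, f))
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i]] | !masks[[i + 1]]))
  }

  expect_error(threshold_mask(img, 1.2), "fraction")
})

test_that("largest-component centroid is accurate and guards small blobs", {
  # lattice disc centred at (100, 60), radius 20 (0-based coordinates)
  xs <- matrix(rep(0:199, each = 120), 120, 200)
  ys <- matrix(rep(0:119, times = 200), 120, 200)
  mask <- (xs - 100)^2 + (ys - 60)^2 <= 20^2
  det <- largest_component_centroid(mask)
  expect_true(det$ok)
  expect_lt(abs(det$cx - 100), 0.1)
  expect_lt(abs(det$cy - 60), 0.1)
  expect_lt(abs(det$radius_px - 20), 0.3)

  # two components: the larger one wins
  m2 <- matrix(FALSE, 60, 60)
  m2[2:26, 2:21] <- TRUE            # 500 px at centre (11.5, 13) 0-based
  m2[40:45, 50:54] <- TRUE          # 30 px
  det2 <- largest_component_centroid(m2)
  expect_equal(det2$area_px, 500)
  expect_equal(det2$cx, 10.5)  # cols 2..21 are x = 1..20, mean 10.5
  expect_equal(det2$cy, 13)    # rows 2..26 are y = 1..25, mean 13

  # a lone pixel fails the min-area guard; empty masks fail without error
  m3 <- matrix(FALSE, 10, 10)
  m3[8, 6] <- TRUE
  expect_false(largest_component_centroid(m3, min_area = 25)$ok)
  expect_false(largest_component_centroid(matrix(FALSE, 5, 5))$ok)
})

test_that("fused detection path equals the composed public primitives", {
  set.seed(21)
  cfg <- detection_config()
  for (case in 1:8) {
    img <- matrix(sample(0:255, 40 * 50, replace = TRUE), 40, 50)
    # sprinkle a blob so there is something to find
    img[10:20, 15:25] <- 250L
    den <- median_denoise(img, cfg$median_window)
    mask <- threshold_mask(den, cfg$threshold_fraction)
    ref <- largest_component_centroid(mask, cfg$min_area)
    fused <- gantrycam:::detect_one_core(img, cfg)
    expect_equal(fused$cx, ref$cx)
    expect_equal(fused$cy, ref$cy)
    expect_equal(fused$area, ref$area_px)
    expect_equal(fused$ok, ref$ok)
  }
})

test_that("detect_dots localizes rendered dots to sub-pixel accuracy", {
  scene <- scene_config(image_w = 640, image_h = 480,
                        center_x = 300, center_y = 300,
                        red_radius_px = 40, green_radius_px = 25,
                        dot_separation_px = 200)
  fr <- render_frame(scene, 0, noise_off())
  pair <- detect_dots(fr)
  red <- pair[pair$colour == "red", ]
  green <- pair[pair$colour == "green", ]
  expect_true(red$ok && green$ok)
  expect_lt(abs(red$cx - 300), 0.3)
  expect_lt(abs(red$cy - 200), 0.3)
  expect_lt(abs(green$cx - 300), 0.3)
  expect_lt(abs(green$cy - 400), 0.3)
  expect_equal(attr(pair, "separation_px"), 200, tolerance = 0.01)
})

test_that("radius fallback labels grey discs and blank frames fail cleanly", {
  grey <- test_scene(red_rgb = c(80, 80, 80), green_rgb = c(80, 80, 80))
  fr <- render_frame(grey, 0, noise_off())
  pair <- detect_dots(fr)
  red <- pair[pair$colour == "red", ]
  green <- pair[pair$colour == "green", ]
  expect_true(red$ok && green$ok)
  expect_gt(red$radius_px, green$radius_px)  # larger disc labelled red
  expect_lt(abs(red$cy - 60), 0.5)           # red on top at gantry 0

  blank <- new_frame(array(255L, c(60, 80, 3)))
  pb <- detect_dots(blank)
  expect_false(any(pb$ok))
})

test_that("detection is deterministic and translation-equivariant", {
  fr <- render_frame(test_scene(), 33, test_noise())
  expect_identical(detect_dots(fr), detect_dots(fr))

  # integer-shift the pixel array; centroids must shift exactly with it
  px <- fr$pixels
  dx <- 7L
  dy <- 4L
  shifted <- array(255L, dim(px))
  shifted[(1 + dy):dim(px)[1], (1 + dx):dim(px)[2], ] <-
    px[1:(dim(px)[1] - dy), 1:(dim(px)[2] - dx), ]
  p0 <- detect_dots(fr)
  p1 <- detect_dots(new_frame(shifted))
  expect_equal(p1$cx, p0$cx + dx, tolerance = 1e-12)
  expect_equal(p1$cy, p0$cy + dy, tolerance = 1e-12)
})
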