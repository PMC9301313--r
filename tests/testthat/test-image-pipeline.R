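test_that("ROI detection recovers the true pad interior on synthetic images", {
  g <- assay_geometry()
  img <- render_device_image(2.0, g, noiseless_params(), seed = 1)
  r <- detect_roi(img)
  expect_gte(region_iou(r, true_pad_interior(img)), 0.8)
  # with noise and jitter it still localises the pad
  img2 <- render_device_image(5.0, g, generator_params(noise_sigma = 6), seed = 3)
  expect_gte(region_iou(detect_roi(img2), true_pad_interior(img2)), 0.8)
  # every panel can be requested; compare against that panel's pad interior
  for (k in 0:2) {
    gk <- g
    gk$active_panel_index <- k
    imgk <- structure(img, truth = list(concentration = 0, geometry = gk,
                                        seed = 1L))
    expect_gte(region_iou(detect_roi(img, panel_index = k),
                          true_pad_interior(imgk)), 0.8)
  }
})

test_that("ROI detection fails loudly on images without a pad", {
  black <- array(0L, dim = c(100, 150, 3))
  expect_error(detect_roi(black), "pad not found")
  noise_only <- array(as.integer(round(runif(100 * 150 * 3, 0, 255))),
                      dim = c(100, 150, 3))
  expect_error(detect_roi(noise_only), "pad not found")
})

test_that("ROI detection is equivariant to in-frame translation", {
  g <- assay_geometry()
  p <- noiseless_params()
  img <- render_device_image(3.0, g, p, seed = 1)
  r0 <- detect_roi(img)
  # translate the whole scene by (+15, +10) px against the uniform background
  arr <- unclass(img)
  shifted <- arr
  for (ch in 1:3) shifted[, , ch] <- round(generator_params()$background_color[ch])
  shifted[11:400, 16:600, ] <- arr[1:390, 1:585, ]
  r1 <- detect_roi(shifted)
  expect_lte(abs(r1$x0 - (r0$x0 + 15)), 1)
  expect_lte(abs(r1$y0 - (r0$y0 + 10)), 1)
  expect_lte(abs(r1$x1 - (r0$x1 + 15)), 1)
  expect_lte(abs(r1$y1 - (r0$y1 + 10)), 1)
})

test_that("patch extraction is pixel-exact, idempotent, and bounds-checked", {
  img <- render_device_image(1.0, assay_geometry(), generator_params(), seed = 2)
  d <- dim(img)
  full <- extract_patch(img, pixel_region(0, 0, d[2], d[1]))
  expect_equal(unclass(full), unclass(img), ignore_attr = TRUE)
  one <- extract_patch(img, pixel_region(10, 20, 11, 21))
  expect_equal(as.vector(one), as.vector(unclass(img)[21, 11, ]))
  again <- extract_patch(full, pixel_region(0, 0, d[2], d[1]))
  expect_equal(unclass(again), unclass(full), ignore_attr = TRUE)
  expect_error(extract_patch(img, pixel_region(0, 0, d[2] + 1, d[1])), "bounds")
})

test_that("color-space conversions hit the standard reference points", {
  mk <- function(rgb) array(rep(rgb, each = 4), dim = c(2, 2, 3))
  w <- convert_color_spaces(mk(c(255, 255, 255)))
  expect_equal(w$LAB[1, 1, 1], 100, tolerance = 1e-6)
  expect_lt(abs(w$LAB[1, 1, 2]), 0.01)
  expect_lt(abs(w$LAB[1, 1, 3]), 0.01)
  expect_equal(w$HSV[1, 1, 2], 0)   # S
  expect_equal(w$HSV[1, 1, 3], 1)   # V

  r <- convert_color_spaces(mk(c(255, 0, 0)))
  expect_equal(r$HSV[1, 1, 1], 0)   # hue 0 degrees
  expect_equal(r$HSV[1, 1, 2], 1)
  expect_equal(r$HSV[1, 1, 3], 1)

  gray <- convert_color_spaces(mk(c(128, 128, 128)))
  expect_lt(abs(gray$LAB[1, 1, 2]), 0.5)
  expect_lt(abs(gray$LAB[1, 1, 3]), 0.5)
  expect_equal(gray$HSV[1, 1, 1], 0)  # achromatic hue reported as 0
})

test_that("RGB -> HSV -> RGB round trip is identity within one 8-bit unit", {
  grid <- as.matrix(expand.grid(r = c(0, 51, 128, 204, 255),
                                g = c(0, 64, 160, 255),
                                b = c(0, 90, 200, 255)))
  arr <- array(0, dim = c(nrow(grid), 1, 3))  # one pixel per row
  for (ch in 1:3) arr[, 1, ch] <- grid[, ch]
  hsv <- convert_color_spaces(arr)$HSV
  back <- grDevices::col2rgb(grDevices::hsv(hsv[, 1, 1] / 360,
                                            hsv[, 1, 2], hsv[, 1, 3]))
  expect_true(all(abs(t(back) - grid) <= 1))
})

test_that("channel statistics are the advertised 36 and match hand values", {
  # constant patch: mean = median = mode on every channel
  const <- array(rep(c(40, 80, 120), each = 9), dim = c(3, 3, 3))
  f <- channel_statistics(const)
  expect_length(f, 36)
  expect_named(f)
  bin_widths <- list(RGB = rep(1, 3), XYZ = c(0.9505, 1, 1.089) / 256,
                     LAB = c(100, 255, 255) / 256, HSV = c(360, 1, 1) / 256)
  for (sp in c("RGB", "XYZ", "LAB", "HSV")) {
    for (ch in 0:2) {
      v <- unclass(f)[sprintf("%s_%d_%s", sp, ch, c("mean", "median", "mode"))]
      expect_equal(v[[1]], v[[2]])  # mean == median on a constant patch
      # the binned mode agrees to within its bin's half width
      expect_lte(abs(v[[3]] - v[[1]]), 0.71 * bin_widths[[sp]][ch + 1])
    }
  }

  # 2 x 2 patch, red channel {10, 10, 20, 40}: mean 20, median 15, mode 10
  patch <- array(0, dim = c(2, 2, 3))
  patch[, , 1] <- c(10, 10, 20, 40)
  f2 <- unclass(channel_statistics(patch))
  expect_equal(f2[["RGB_0_mean"]], 20)
  expect_equal(f2[["RGB_0_median"]], 15)
  expect_equal(f2[["RGB_0_mode"]], 10)
})

test_that("channel statistics ignore pixel order", {
  set.seed(42)
  vals <- sample(0:255, 48, replace = TRUE)
  a <- array(vals, dim = c(4, 4, 3))
  perm <- sample(16)
  b <- a
  for (ch in 1:3) b[, , ch] <- matrix(as.vector(a[, , ch])[perm], 4, 4)
  expect_equal(unclass(channel_statistics(a)), unclass(channel_statistics(b)))
})
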