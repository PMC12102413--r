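test_that("overview level follows the 2.5x effective-magnification rule", {
  expect_identical(select_overview_level(80), 5L)
  expect_identical(select_overview_level(40), 4L)
  expect_identical(select_overview_level(20), 3L)
  expect_identical(select_overview_level(2.5), 0L)
  # doubling the magnification adds one level
  for (mag in c(2.5, 5, 10, 20, 40, 80))
    expect_identical(select_overview_level(2 * mag),
                     select_overview_level(mag) + 1L)
  # clamped to the available levels
  pyr <- build_pyramid(matrix(runif(64 * 64, 0, 255), 64, 64), 3, mpp = 0.25)
  expect_identical(select_overview_level(80, pyr), 2L)
  expect_error(select_overview_level(0), "positive")
  expect_error(select_overview_level(-40), "positive")
})

test_that("physical unit conversions are exact", {
  expect_equal(microns_to_pixels(3.4, 0.25), 13.6)
  expect_equal(microns_to_pixels(0, 0.31), 0)
  expect_equal(microns_to_pixels(1.0, 0.2272), 1 / 0.2272)
  expect_error(microns_to_pixels(1, 0), "positive")
  # inverse relation up to float rounding
  d <- c(0.3, 3.4, 120)
  expect_equal(microns_to_pixels(d, 0.2454) * 0.2454, d)
})

test_that("relative scale percent reproduces inter-scanner size differences", {
  # Hamamatsu XR (0.2272 mpp) vs 3DHISTECH P150 (0.2744 mpp): structures
  # appear roughly 20 % larger on the coarser scanner
  v <- relative_scale_percent(0.2744, 0.2272)
  expect_equal(round(v), 21)
  expect_gt(v, 20); expect_lt(v, 21)
  expect_equal(relative_scale_percent(0.25, 0.25), 0)
  expect_equal(relative_scale_percent(0.5, 0.25), 100)
  expect_error(relative_scale_percent(-1, 1), "positive")
})

test_that("build_pyramid halves dimensions with anti-aliasing", {
  base <- matrix(runif(256 * 256, 0, 255), 256, 256)
  p1 <- build_pyramid(base, 1, mpp = 0.25)
  expect_length(p1$levels, 1)
  p3 <- build_pyramid(base, 3, mpp = 0.25)
  expect_equal(sapply(p3$levels, nrow), c(256, 128, 64))
  expect_equal(sapply(p3$levels, ncol), c(256, 128, 64))
  # smooth image: level-1 mean within 1 % of base mean
  sm <- cpp_gauss_blur(base, 4)
  ps <- build_pyramid(sm, 2, mpp = 0.25)
  expect_lt(abs(mean(ps$levels[[2]]) - mean(sm)) / mean(sm), 0.01)
  # odd dimensions follow ceiling(previous / 2)
  podd <- build_pyramid(matrix(0, 101, 67), 2, mpp = 0.25)
  expect_equal(dim(podd$levels[[2]]), c(51, 34))
  expect_error(build_pyramid(base, 20, mpp = 0.25), "n_levels")
  expect_error(pyramid_image(list(base), mpp_x = -1), "mpp")
})

test_that("read_region reads, scales and pads with a clipped flag", {
  sl <- small_slide()
  pyr <- build_pyramid(sl$image, 3, mpp = 0.25)
  full <- read_region(pyr, 0, wsi_rect(0, 0, 256, 256))
  expect_false(attr(full, "clipped"))
  expect_equal(full[, , 1], sl$image[, , 1], ignore_attr = TRUE)
  # interior rect at level 2 equals a direct slice of the level-2 array
  r <- wsi_rect(32, 48, 64, 64)
  reg <- read_region(pyr, 2, r)
  expect_equal(reg[, , 2],
               pyr$levels[[3]][(48 / 4 + 1):(48 / 4 + 16),
                               (32 / 4 + 1):(32 / 4 + 16), 2],
               ignore_attr = TRUE)
  # rect past the right edge: padded with background, flagged
  re <- read_region(pyr, 0, wsi_rect(250, 0, 16, 16), background = 255)
  expect_true(attr(re, "clipped"))
  expect_true(all(re[, 8:16, ] == 255))
  expect_error(read_region(pyr, 0, wsi_rect(500, 500, 10, 10)), "intersect")
  expect_error(read_region(pyr, 9, wsi_rect(0, 0, 10, 10)), "level")
})

test_that("read_region at a level matches reference downsampling of the base", {
  sl <- small_slide()
  pyr <- build_pyramid(to_gray(sl$image), 3, mpp = 0.25)
  r <- wsi_rect(64, 64, 128, 128)
  lvl <- read_region(pyr, 1, r)
  # reference path: read at base, then one blur + decimate step
  base <- read_region(pyr, 0, r)
  sm <- cpp_gauss_blur(base, 2 / 3)
  ref <- sm[seq(1, nrow(sm), 2), seq(1, ncol(sm), 2)]
  expect_lt(mean(abs(lvl - ref)), 2)
})

test_that("pyramidal TIFF and point sets round-trip through disk", {
  sl <- generate_tissue_slide(128, 128, 10, seed = 3)
  pyr <- build_pyramid(sl$image, 3, mpp = 0.2454, magnification = 40)
  tf <- file.path(tempdir(), "pyr.tiff")
  write_pyramid_tiff(pyr, tf)
  back <- read_pyramid_tiff(tf)
  expect_equal(length(back$levels), 3)
  expect_equal(back$mpp_x, 0.2454)
  expect_equal(back$magnification, 40)
  # 8-bit storage: intensities within rounding of the original
  expect_lt(max(abs(back$levels[[1]] - sl$image)), 0.51)
  pts <- data.frame(x = c(1.5, 20), y = c(3, 40.25), label = c("a", "b"))
  pcsv <- file.path(tempdir(), "pts.csv")
  write_points(pts, pcsv)
  expect_equal(read_points(pcsv)$x, pts$x)
  pjson <- file.path(tempdir(), "pts.json")
  write_points(pts, pjson)
  expect_equal(read_points(pjson)$y, pts$y)
})
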