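test_that("coarse registration of a slide against itself is near-identity", {
  pr <- sim_pair()
  roi <- auto_roi(pr$fixed)
  cr <- coarse_register(pr$fixed, pr$fixed, roi, roi, seed = 5)
  expect_lt(abs(cr$transform$angle), 0.2)
  expect_lt(abs(cr$transform$scale - 1), 0.01)
  expect_lt(sqrt(cr$transform$tx^2 + cr$transform$ty^2), 1)
})

test_that("coarse stage recovers a synthetic similarity scenario", {
  pr <- sim_pair()
  roi_f <- auto_roi(pr$fixed)
  roi_m <- auto_roi(pr$moving$pyramid)
  cr <- coarse_register(pr$fixed, pr$moving$pyramid, roi_f, roi_m, seed = 31)
  expect_lt(abs(cr$transform$angle - pr$scenario$angle), 0.5)
  expect_lt(abs(cr$transform$scale * cr$factor_m / cr$factor_f -
                  pr$scenario$scale / pr$scenario$mpp_ratio), 0.01)
  bt <- extrapolate_to_base(cr)
  ctr <- c(255.5, 255.5)
  err_ov <- sqrt(sum((transform_point(bt, ctr) -
                        pr$moving$gt$map(ctr))^2)) / cr$factor_f
  expect_lt(err_ov, 2)
  # end-to-end precision floor before refinement: mean nucleus-center error
  # at most twice the overview downsample factor (in base px)
  truth <- pr$moving$gt$map(pr$slide$centers)
  pred <- transform_point(bt, pr$slide$centers)
  expect_lte(mean(sqrt(rowSums((pred - truth)^2))), 2 * cr$factor_f)
})

test_that("differently placed ROIs still align the tissue", {
  pr <- sim_pair()
  roi_f <- auto_roi(pr$fixed)
  roi_m0 <- auto_roi(pr$moving$pyramid)
  # moving ROI deliberately shifted and padded
  dims_m <- level_dims(pr$moving$pyramid, 0)
  roi_m <- wsi_rect(max(0, roi_m0$x - 24), max(0, roi_m0$y - 40),
                    min(roi_m0$w + 40, dims_m[1]),
                    min(roi_m0$h + 48, dims_m[2]))
  cr <- coarse_register(pr$fixed, pr$moving$pyramid, roi_f, roi_m, seed = 8)
  bt <- extrapolate_to_base(cr)
  ctr <- c(255.5, 255.5)
  err_ov <- sqrt(sum((transform_point(bt, ctr) -
                        pr$moving$gt$map(ctr))^2)) / cr$factor_f
  expect_lt(err_ov, 3)
})

fake_coarse <- function(tr, roi_f, roi_m, ff, fm) {
  structure(list(transform = tr, metric = -1, status = "ok",
                 roi_f = roi_f, roi_m = roi_m, level_f = log2(ff),
                 level_m = log2(fm), factor_f = ff, factor_m = fm),
            class = "coarse_result")
}

test_that("extrapolation rescales overview parameters exactly", {
  r0 <- wsi_rect(0, 0, 4096, 4096)
  # level 0: numerically unchanged
  tr <- similarity_transform(5, 1.02, 3.5, -1.25, c(10, 12))
  bt0 <- extrapolate_to_base(fake_coarse(tr, r0, r0, 1, 1))
  p <- matrix(runif(40, 0, 4000), 20, 2)
  expect_equal(transform_point(bt0, p), transform_point(tr, p),
               tolerance = 1e-9)
  # pure translation (3, 4) at level 5 becomes (96, 128) at the base
  tt <- similarity_transform(0, 1, 3, 4, c(0, 0))
  bt5 <- extrapolate_to_base(fake_coarse(tt, r0, r0, 32, 32))
  expect_equal(c(bt5$tx, bt5$ty), c(96, 128))
  expect_equal(bt5$angle, 0); expect_equal(bt5$scale, 1)
})

test_that("upscale-then-map commutes with map-then-upscale", {
  set.seed(19)
  roi_f <- wsi_rect(320, 144, 2048, 1536)
  roi_m <- wsi_rect(96, 512, 2560, 1792)
  tr <- similarity_transform(-9, 1.07, 6.5, -3.25, c(64, 48))
  cr <- fake_coarse(tr, roi_f, roi_m, 16, 16)
  bt <- extrapolate_to_base(cr)
  p <- cbind(runif(100, 320, 2300), runif(100, 144, 1600))
  manual <- transform_point(tr, sweep(p, 2, c(roi_f$x, roi_f$y)) / 16)
  manual <- sweep(manual * 16, 2, c(roi_m$x, roi_m$y), `+`)
  expect_lt(max(abs(transform_point(bt, p) - manual)), 1e-6)
})

test_that("rotated-region extraction matches its defining crops", {
  pr <- sim_pair()
  pyr <- pr$fixed
  r <- wsi_rect(192, 160, 128, 128)
  # theta = 0: identical to a plain region read
  ex0 <- extract_rotated_region(pyr, r, 0, level = 0)
  expect_equal(unclass(ex0), unclass(read_region(pyr, 0, r)),
               ignore_attr = TRUE, tolerance = 1e-6)
  # theta = 90 on the asymmetric tissue: equals the exact array rotation of
  # the crop read from the pre-rotated slide (interior pixels, right-angle
  # case is lossless)
  ex90 <- extract_rotated_region(pyr, r, 90, level = 0)
  crop <- to_gray(read_region(pyr, 0, r))
  ex90g <- to_gray(ex90)
  rot_crop <- apply_orientation_pretransform(crop, "rot90")
  expect_lt(mean(abs(ex90g[10:119, 10:119] - rot_crop[10:119, 10:119])), 0.5)
})

test_that("arbitrary-angle extraction matches a dense inverse-mapping oracle", {
  pr <- sim_pair()
  base <- to_gray(pr$fixed$levels[[1]])
  r <- wsi_rect(176, 208, 96, 96)
  theta <- 23
  ctr <- rect_center(r)
  ex <- to_gray(extract_rotated_region(pr$fixed, r, theta, level = 0))
  # oracle: bilinear resample of every output pixel straight from the base
  g <- grid_coords(96, 96)
  p <- cbind(r$x + g[, 1], r$y + g[, 2])
  q <- transform_point(similarity_transform(theta, 1, 0, 0, ctr), p)
  oracle <- matrix(cpp_interp(base, q[, 1], q[, 2], 1L, 255), 96, 96)
  expect_lt(mean(abs(ex[5:92, 5:92] - oracle[5:92, 5:92])), 2)
})

test_that("reads beyond the slide are flagged or rejected", {
  pr <- sim_pair()
  r_edge <- wsi_rect(480, 480, 64, 64)
  ex <- extract_rotated_region(pr$fixed, r_edge, 30, level = 0)
  expect_true(attr(ex, "clipped"))
  expect_error(extract_rotated_region(pr$fixed, wsi_rect(5000, 5000, 64, 64),
                                      10),
               "outside")
})
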