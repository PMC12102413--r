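test_that("grids tile the ROI exactly", {
  roi <- wsi_rect(0, 0, 4096, 4096)
  g <- build_grid(roi, tile_size = 2048)
  expect_length(g$tiles, 4)
  g1 <- build_grid(roi, tile_size = 4096)
  expect_length(g1$tiles, 1)
  expect_warning(build_grid(wsi_rect(0, 0, 1000, 1000), tile_size = 2048),
                 "single tile")
  # randomized ROI / tile sizes: count and coverage
  set.seed(23)
  for (i in 1:12) {
    w <- sample(500:4000, 1); h <- sample(500:4000, 1)
    ts <- sample(200:2500, 1)
    roi <- wsi_rect(sample(0:100, 1), sample(0:100, 1), w, h)
    # an occasional tile larger than the ROI exercises the single-tile
    # fallback, whose warning is asserted separately above
    g <- suppressWarnings(build_grid(roi, tile_size = ts))
    ts <- min(ts, max(w, h))
    expect_length(g$tiles, ceiling(w / ts) * ceiling(h / ts))
    # union of tiles covers the ROI: brute-force corner check
    xs <- seq(roi$x, roi$x + w - 1, length.out = 13)
    ys <- seq(roi$y, roi$y + h - 1, length.out = 13)
    pts <- as.matrix(expand.grid(x = xs, y = ys))
    covered <- rep(FALSE, nrow(pts))
    for (tl in g$tiles) {
      r <- tl$rect
      covered <- covered | (pts[, 1] >= r$x & pts[, 1] < r$x + r$w &
                              pts[, 2] >= r$y & pts[, 2] < r$y + r$h)
    }
    expect_true(all(covered))
  }
})

test_that("tile retention and pixel accounting follow the annotations", {
  roi <- wsi_rect(0, 0, 4096, 4096)
  ann <- data.frame(x = c(100, 150, 3000), y = c(100, 180, 3000))
  g <- build_grid(roi, tile_size = 2048, annotations = ann)
  expect_equal(sum(g$retained), 2)
  expect_equal(count_registered_pixels(4, 4096) / 1e6, 67.108864)
  expect_equal(count_registered_pixels(10, 4096) / 1e6, 167.77216)
  expect_equal(count_registered_pixels(10, 2048) / 1e6, 41.94304)
  expect_equal(count_registered_pixels(1, 1), 1)
  expect_equal(format_megapixels(count_registered_pixels(4, 4096)),
               "67.11 million")
  # retained-tile pixel sum is exactly tiles x tile^2
  expect_equal(sum(vapply(g$tiles[g$retained],
                          function(tl) tl$rect$w * tl$rect$h, numeric(1))),
               count_registered_pixels(2, 2048))
})

test_that("identity pairs give near-identity per-tile transforms", {
  pr <- sim_pair()
  roi <- wsi_rect(128, 128, 256, 256)
  ann <- generate_annotations(10, "clustered",
                              wsi_rect(160, 160, 192, 192), seed = 2)
  grid <- build_grid(roi, tile_size = 128, annotations = ann)
  tiles <- refine_tiles_strategy1(grid, identity_transform(), pr$fixed,
                                  pr$fixed,
                                  config = reg_config(n_resolutions = 1,
                                                      iterations = 300,
                                                      n_samples = 2048),
                                  seed = 3)
  for (tl in tiles) {
    expect_equal(tl$status, "ok")
    ctr <- rect_center(tl$rect)
    expect_lt(sqrt(sum((transform_point(tl$transform, ctr) - ctr)^2)), 0.5)
  }
})

test_that("per-point correction recovers an injected local offset", {
  pr <- sim_pair()
  # construct a pure-translation pair: moving content = fixed shifted
  sl <- pr$slide
  mvp <- derive_moving_slide(sl, slide_scenario(tx = 2, ty = -1.5),
                             mpp = 0.25, magnification = 20, n_levels = 5)
  p <- c(256, 240)
  pc <- refine_point_strategy2(p, identity_transform(), pr$fixed,
                               mvp$pyramid, patch_size = 128,
                               config = reg_config(n_resolutions = 1,
                                                   iterations = 300,
                                                   n_samples = 2048),
                               seed = 77, id = 1)
  expect_equal(pc$status, "ok")
  truth <- mvp$gt$map(p)
  expect_lt(sqrt(sum((pc$corrected - truth)^2)), 0.5)
  # identity pair: corrected point stays put
  pc0 <- refine_point_strategy2(p, identity_transform(), pr$fixed, pr$fixed,
                                patch_size = 128,
                                config = reg_config(n_resolutions = 1,
                                                    iterations = 300,
                                                    n_samples = 2048),
                                seed = 78, id = 1)
  expect_lt(sqrt(sum((pc0$corrected - p)^2)), 0.25)
})

test_that("edge annotations are flagged and keep the coarse coordinate", {
  pr <- sim_pair()
  p <- c(20, 20)  # within patch_size/2 of the slide edge
  pc <- refine_point_strategy2(p, identity_transform(), pr$fixed, pr$fixed,
                               patch_size = 128, id = 9)
  expect_equal(pc$status, "out_of_bounds")
  expect_equal(pc$corrected, p)
  expect_error(refine_point_strategy2(c(256, 256), identity_transform(),
                                      pr$fixed, pr$fixed, patch_size = 32),
               "patch_size")
})

test_that("strategy choice matches a direct cost comparison", {
  roi <- wsi_rect(0, 0, 20000, 20000)
  dense <- data.frame(x = runif(100, 0, 1800), y = runif(100, 0, 1800))
  expect_equal(choose_strategy(dense, roi)$recommendation, "strategy1")
  sparse <- data.frame(x = seq(100, 19900, length.out = 100),
                       y = seq(19900, 100, length.out = 100))
  expect_equal(choose_strategy(sparse, roi)$recommendation, "strategy2")
  set.seed(41)
  for (i in 1:10) {
    pts <- data.frame(x = runif(30, 0, 20000), y = runif(30, 0, 20000))
    cs <- choose_strategy(pts, roi, tile_size = 2048, patch_size = 192)
    g <- build_grid(roi, tile_size = 2048, annotations = pts)
    manual1 <- sum(g$retained) * 2048^2
    manual2 <- 30 * 192^2 * 4
    expect_equal(cs$recommendation,
                 if (manual1 < manual2) "strategy1" else "strategy2")
  }
})

test_that("refinement halves the colocalization error of the coarse stage", {
  # deformation-dominated scenario: a strong smooth re-staining deformation
  # (amplitude 8 px, smoothness 150 px) and an annotation cluster away from
  # the tissue center, so the local displacement is not absorbed by the
  # global similarity. This is the regime the base-layer refinement exists
  # for; both strategies must at least halve the coarse stage's mean error.
  cfg <- reg_config(n_resolutions = 1, iterations = 200, n_samples = 1024)
  coarse_errs <- c(); e1s <- c(); e2s <- c(); e12s <- c()
  for (s in 1:3) {
    sl <- generate_tissue_slide(512, 512, 90, seed = 50 + s)
    fixed <- build_pyramid(sl$image, 5, mpp = 0.25, magnification = 20)
    set.seed(60 + s)
    sc <- slide_scenario(angle = runif(1, -6, 6), scale = runif(1, 0.98, 1.04),
                         tx = runif(1, -20, 20), ty = runif(1, -20, 20),
                         deform_amplitude = 8, deform_smoothness = 150,
                         seed = 160 + s)
    mv <- derive_moving_slide(sl, sc, mpp = 0.25, magnification = 20,
                              n_levels = 5)
    ann <- generate_annotations(12, "clustered", wsi_rect(300, 150, 110, 110),
                                seed = 70 + s)
    truth <- mv$gt$map(cbind(ann$x, ann$y))
    tdf <- data.frame(id = ann$id, x = truth[, 1], y = truth[, 2])
    fit1 <- register_slides(fixed, mv$pyramid, ann, strategy = "1",
                            tile_size = 96, refine_config = cfg,
                            seed = 80 + s)
    coarse_errs <- c(coarse_errs, mean(sqrt(rowSums(
      (transform_point(fit1$base_transform, cbind(ann$x, ann$y)) - truth)^2))))
    e1 <- colocalization_error(predict(fit1), tdf, 0.25)$summary_px[["mean"]]
    e1s <- c(e1s, e1)
    fit2 <- register_slides(fixed, mv$pyramid, ann, strategy = "2",
                            patch_size = 128, refine_config = cfg,
                            seed = 80 + s)
    e2s <- c(e2s, colocalization_error(predict(fit2), tdf,
                                       0.25)$summary_px[["mean"]])
    # optional prior refinement: per-point corrections run after the
    # per-tile stage must not increase the error
    grid <- build_grid(fit1$roi_fixed, tile_size = 96, annotations = ann)
    idx <- grid_tile_index(grid, cbind(ann$x, ann$y))
    tile_tr <- lapply(fit1$refinement$tiles, `[[`, "transform")
    tile_ids <- vapply(fit1$refinement$tiles, `[[`, numeric(1), "index")
    after <- t(vapply(seq_len(nrow(ann)), function(i) {
      tt <- tile_tr[[match(idx[i], tile_ids)]]
      comp <- compose_transforms(fit1$base_transform, tt)
      pc <- refine_point_strategy2(c(ann$x[i], ann$y[i]), comp, fixed,
                                   mv$pyramid, patch_size = 128,
                                   config = cfg, seed = 90 + i, id = ann$id[i])
      pc$corrected
    }, numeric(2)))
    e12s <- c(e12s, mean(sqrt(rowSums((after - truth)^2))))
  }
  expect_gte(mean(coarse_errs) / mean(e1s), 2)
  expect_gte(mean(coarse_errs) / mean(e2s), 2)
  expect_lte(mean(e12s), mean(e1s) * 1.1 + 0.3)
})

test_that("smooth deformation leaves larger residuals at tile corners", {
  sl <- generate_tissue_slide(512, 512, 90, seed = 55)
  fixed <- build_pyramid(sl$image, 5, mpp = 0.25, magnification = 20)
  sc <- slide_scenario(deform_amplitude = 5, deform_smoothness = 120,
                       seed = 66)
  mv <- derive_moving_slide(sl, sc, mpp = 0.25, magnification = 20,
                            n_levels = 5)
  roi <- wsi_rect(128, 128, 256, 256)
  ann <- data.frame(x = c(192, 320), y = c(192, 320))
  grid <- build_grid(roi, tile_size = 128, annotations = ann)
  tiles <- refine_tiles_strategy1(grid, identity_transform(), fixed,
                                  mv$pyramid,
                                  config = reg_config(n_resolutions = 1,
                                                      iterations = 200,
                                                      n_samples = 1024),
                                  seed = 5)
  center_err <- c(); corner_err <- c()
  for (tl in tiles) {
    if (tl$status != "ok") next
    r <- tl$rect
    ctr <- rect_center(r)
    corners <- rbind(c(r$x + 4, r$y + 4), c(r$x + r$w - 4, r$y + r$h - 4))
    map_pred <- function(p) transform_point(tl$transform, p)
    center_err <- c(center_err,
                    sqrt(sum((map_pred(ctr) - mv$gt$map(ctr))^2)))
    corner_err <- c(corner_err, mean(sqrt(rowSums(
      (map_pred(corners) - mv$gt$map(corners))^2))))
  }
  expect_lt(mean(center_err), mean(corner_err))
})
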