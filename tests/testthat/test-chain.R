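test_that("empty and translation-only chains behave algebraically", {
  ch0 <- compose_chain()
  pts <- data.frame(id = 1:3, x = c(1, 10.4, 100), y = c(2, 20.6, 200))
  out <- apply_chain(pts, ch0)
  expect_equal(out$x, c(1, 10, 100))
  expect_equal(out$y, c(2, 21, 200))
  ch <- compose_chain(list(
    chain_step_global(similarity_transform(0, 1, 1, 2), created = 1),
    chain_step_global(similarity_transform(0, 1, 3, 4), created = 2)))
  out2 <- apply_chain(pts, ch, discrete = FALSE)
  expect_equal(out2$x, pts$x + 4)
  expect_equal(out2$y, pts$y + 6)
})

test_that("chain application equals sequential manual application", {
  set.seed(3)
  t1 <- similarity_transform(17, 1.06, 5, -8, c(40, 60))
  t2 <- affine_transform(matrix(c(1.01, 0.02, -0.015, 0.99), 2, 2), 1, 2)
  ch <- compose_chain(list(chain_step_global(t1, created = 1),
                           chain_step_global(t2, created = 2)))
  pts <- data.frame(id = seq_len(1000), x = runif(1000, 0, 500),
                    y = runif(1000, 0, 500))
  out <- apply_chain(pts, ch, discrete = FALSE)
  manual <- transform_point(t2, transform_point(t1, cbind(pts$x, pts$y)))
  expect_equal(cbind(out$x, out$y), manual, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("rounding is half-to-even and bounded by half a pixel", {
  pts <- data.frame(id = 1:2, x = c(10.5, 11.5), y = c(20.5, -0.5))
  out <- apply_chain(pts, compose_chain())
  expect_equal(out$x, c(10, 12))
  expect_equal(out$y, c(20, 0))
  set.seed(5)
  p2 <- data.frame(id = 1:50, x = runif(50, 0, 100), y = runif(50, 0, 100))
  cont <- apply_chain(p2, compose_chain(), discrete = FALSE)
  disc <- apply_chain(p2, compose_chain(), discrete = TRUE)
  expect_true(all(abs(cont$x - disc$x) <= 0.5 + 1e-12))
  expect_true(all(abs(cont$y - disc$y) <= 0.5 + 1e-12))
})

test_that("chains refuse invalid construction", {
  t1 <- chain_step_global(identity_transform(), created = 2)
  t2 <- chain_step_global(identity_transform(), created = 1)
  expect_error(compose_chain(list(t1, t2)), "creation order")
  overlapping <- chain_step_tiles(
    list(list(rect = wsi_rect(0, 0, 100, 100),
              correction = identity_transform(), status = "ok",
              row = 0, col = 0),
         list(rect = wsi_rect(50, 50, 100, 100),
              correction = identity_transform(), status = "ok",
              row = 0, col = 1)),
    wsi_rect(0, 0, 150, 150), 100, 100, c(2, 1), created = 1)
  expect_error(compose_chain(list(overlapping)), "overlap")
  dup <- chain_step_points(list(
    list(id = 1, status = "ok", correction = identity_transform()),
    list(id = 1, status = "ok", correction = identity_transform())),
    created = 1)
  expect_error(compose_chain(list(dup)), "duplicate")
})

test_that("tile membership routes points through their own tile only", {
  base <- similarity_transform(0, 1, 10, 0)
  c1 <- similarity_transform(0, 1, 1, 1)    # tile 1 correction
  c2 <- similarity_transform(0, 1, -2, 5)   # tile 2 correction
  step <- chain_step_tiles(
    list(list(rect = wsi_rect(0, 0, 100, 100), correction = c1,
              status = "ok", row = 0, col = 0),
         list(rect = wsi_rect(100, 0, 100, 100), correction = c2,
              status = "ok", row = 0, col = 1)),
    wsi_rect(0, 0, 200, 100), 100, 100, c(2, 1), created = 2)
  ch <- compose_chain(list(chain_step_global(base, created = 1), step),
                      strategy = "1")
  pts <- data.frame(id = 1:3, x = c(50, 150, 500), y = c(50, 50, 50))
  out <- apply_chain(pts, ch, discrete = FALSE)
  expect_equal(c(out$x[1], out$y[1]), c(61, 51))    # base + c1
  expect_equal(c(out$x[2], out$y[2]), c(158, 55))   # base + c2
  # outside all tiles: base transform only, flagged
  expect_equal(c(out$x[3], out$y[3]), c(510, 50))
  expect_equal(out$flag, c("ok", "ok", "outside_tiles"))
})

test_that("chains serialize to JSON and reload bit-exactly", {
  sf <- strategy1_fit()
  fit <- sf$fit; ann <- sf$ann
  path <- file.path(tempdir(), "chain.json")
  write_chain(fit$chain, path)
  back <- read_chain(path)
  out1 <- apply_chain(ann, fit$chain)
  out2 <- apply_chain(ann, back)
  expect_identical(out1$x, out2$x)
  expect_identical(out1$y, out2$y)
  # reusable on new points without re-registration
  new_pts <- generate_annotations(8, "clustered",
                                  wsi_rect(180, 180, 150, 150), seed = 9)
  r1 <- reuse_chain(new_pts, fit$chain)
  r2 <- reuse_chain(new_pts, back)
  expect_identical(r1, r2)
})

test_that("strategy-II chains refuse unseen annotations", {
  corr <- chain_step_points(list(
    list(id = 1, status = "ok", correction = identity_transform()),
    list(id = 2, status = "ok", correction = identity_transform())),
    created = 2)
  ch <- compose_chain(list(chain_step_global(identity_transform(),
                                             created = 1), corr),
                      strategy = "2")
  known <- data.frame(id = c(1, 2), x = c(5, 6), y = c(7, 8))
  expect_silent(reuse_chain(known, ch))
  unseen <- data.frame(id = c(1, 3), x = c(5, 6), y = c(7, 8))
  expect_error(reuse_chain(unseen, ch), "not reusable")
})

test_that("smoothed tile fields stay close to piecewise application", {
  base <- similarity_transform(0, 1, 5, 5)
  mk <- function(dx, dy, row, col)
    list(rect = wsi_rect(col * 100, row * 100, 100, 100),
         correction = similarity_transform(0, 1, dx, dy), status = "ok",
         row = row, col = col)
  tiles <- list(mk(1, 0, 0, 0), mk(1.2, 0.1, 0, 1),
                mk(0.9, -0.1, 1, 0), mk(1.1, 0, 1, 1))
  ch <- compose_chain(list(chain_step_global(base, created = 1),
                           chain_step_tiles(tiles, wsi_rect(0, 0, 200, 200),
                                            100, 100, c(2, 2), created = 2)),
                      strategy = "1")
  pts <- data.frame(id = 1:4, x = c(50, 150, 50, 100), y = c(50, 50, 150, 100))
  hard <- apply_chain(pts, ch, discrete = FALSE, smooth = FALSE)
  soft <- apply_chain(pts, ch, discrete = FALSE, smooth = TRUE)
  # at tile centers the smoothed field reproduces the tile displacement
  expect_equal(soft$x[1], hard$x[1], tolerance = 0.15)
  # everywhere the smoothed correction stays within the tile-sample range
  expect_true(all(soft$x - pts$x - 5 >= 0.9 - 0.05 &
                    soft$x - pts$x - 5 <= 1.2 + 0.05))
})
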