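# Base-layer refinement. Strategy I registers a grid of large tiles and is
# economical when annotations cluster in a compact region; Strategy II
# registers a small patch around every single annotation and wins when
# annotations are spread out. Both refine the coarse base transform; per
# tile/point failures fall back to the coarse transform so that no point is
# ever lost.

#' Build the fixed-side refinement grid
#'
#' Row-major grid of equal tiles covering the ROI; tiles in the last row and
#' column may extend past the ROI and are clipped at read time. When an
#' annotation set is supplied, only tiles containing at least one annotation
#' are retained (half-open tile rects; a boundary point belongs to the tile
#' with the lower row-major index).
#'
#' @param roi ROI [wsi_rect()] in base coordinates.
#' @param tile_size square tile side in px (give exactly one of `tile_size`
#'   and `n_tiles`).
#' @param n_tiles approximate number of grid sections.
#' @param annotations optional data frame with `x`, `y`.
#' @return A `grid_tiles` object.
#' @export
build_grid <- function(roi, tile_size = NULL, n_tiles = NULL,
                       annotations = NULL) {
  stopifnot(inherits(roi, "wsi_rect"))
  if (is.null(tile_size) == is.null(n_tiles))
    stop("give exactly one of tile_size or n_tiles")
  if (!is.null(n_tiles)) {
    stopifnot(n_tiles >= 1)
    nx <- max(1, round(sqrt(n_tiles * roi$w / roi$h)))
    ny <- max(1, ceiling(n_tiles / nx))
    tw <- ceiling(roi$w / nx); th <- ceiling(roi$h / ny)
  } else {
    if (tile_size > max(roi$w, roi$h)) {
      warning("tile_size exceeds the ROI; using a single tile")
      tile_size <- max(roi$w, roi$h)
    }
    tw <- th <- tile_size
    nx <- ceiling(roi$w / tw); ny <- ceiling(roi$h / th)
  }
  tiles <- vector("list", nx * ny)
  k <- 0
  for (iy in 0:(ny - 1)) {
    for (ix in 0:(nx - 1)) {
      k <- k + 1
      tiles[[k]] <- list(index = k, row = iy, col = ix,
                         rect = wsi_rect(roi$x + ix * tw, roi$y + iy * th,
                                         tw, th))
    }
  }
  retained <- rep(TRUE, length(tiles))
  if (!is.null(annotations)) {
    pts <- as.matrix(annotations[, c("x", "y")])
    retained <- vapply(tiles, function(tl) {
      r <- tl$rect
      any(pts[, 1] >= r$x & pts[, 1] < r$x + r$w &
            pts[, 2] >= r$y & pts[, 2] < r$y + r$h)
    }, logical(1))
  }
  structure(list(tiles = tiles, retained = retained, roi = roi,
                 tile_w = tw, tile_h = th, nx = nx, ny = ny),
            class = "grid_tiles")
}

#' @export
print.grid_tiles <- function(x, ...) {
  cat(sprintf("<grid: %d x %d tiles of %g x %g px, %d retained>\n",
              x$nx, x$ny, x$tile_w, x$tile_h, sum(x$retained)))
  invisible(x)
}

# row-major index of the tile containing each point, NA when outside
grid_tile_index <- function(grid, pts) {
  pts <- as.matrix(pts)
  ix <- floor((pts[, 1] - grid$roi$x) / grid$tile_w)
  iy <- floor((pts[, 2] - grid$roi$y) / grid$tile_h)
  ok <- ix >= 0 & ix < grid$nx & iy >= 0 & iy < grid$ny
  idx <- iy * grid$nx + ix + 1
  idx[!ok] <- NA
  idx
}

#' Total pixels registered by a tiling
#'
#' `n_tiles * tile_size^2`; run logs report it in millions with two
#' decimals.
#'
#' @param n_tiles number of tiles (>= 1).
#' @param tile_size square tile side in px.
#' @export
count_registered_pixels <- function(n_tiles, tile_size) {
  stopifnot(n_tiles >= 1)
  n_tiles * tile_size^2
}

format_megapixels <- function(pixels) sprintf("%.2f million", pixels / 1e6)

# convert a transform estimated on a level-f crop with origin o (base
# coords) into the equivalent base-frame transform
local_to_base_transform <- function(tr, origin, f) {
  c_base <- origin + f * tr$center
  if (inherits(tr, "affine_transform")) {
    t_base <- f * (tr$center + c(tr$tx, tr$ty)) + origin - c_base
    affine_transform(tr$A, t_base[1], t_base[2], c_base)
  } else {
    t_base <- f * (tr$center + c(tr$tx, tr$ty)) + origin - c_base
    similarity_transform(tr$angle, tr$scale, t_base[1], t_base[2], c_base)
  }
}

#' Strategy I: per-tile refinement registration
#'
#' For every retained grid tile, reads the fixed tile, extracts the
#' corresponding rotation- and scale-compensated moving region through the
#' coarse base transform, and registers the two with a reduced budget
#' (rigid by default). A failed tile falls back to the base transform with
#' its status recorded; per-tile failures never abort the run.
#'
#' @param grid a `grid_tiles` from [build_grid()].
#' @param base_tr the base-layer `similarity_transform` from
#'   [extrapolate_to_base()].
#' @param fixed,moving `pyramid_image`s.
#' @param config refinement [reg_config()] (reduced budget).
#' @param model per-tile transform model (default `"rigid"`).
#' @param level_f,level_m resolution levels used for the refinement reads
#'   of the fixed and moving slide (matched mpp when magnifications differ).
#' @param seed RNG seed.
#' @return List of per-tile results (`rect`, `transform` in the base frame,
#'   `status`, `metric`), one per retained tile.
#' @export
refine_tiles_strategy1 <- function(grid, base_tr, fixed, moving,
                                   config = reg_config(n_resolutions = 2,
                                                       iterations = 250),
                                   model = "rigid", level_f = 0, level_m = 0,
                                   seed = NULL) {
  f <- fixed$downsample_factors[level_f + 1]
  res <- list()
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, sum(grid$retained)))
  j <- 0
  for (tl in grid$tiles[grid$retained]) {
    j <- j + 1
    out <- tryCatch({
      fimg <- to_gray(read_region(fixed, level_f, tl$rect))
      mimg <- to_gray(extract_mapped_region(moving, tl$rect, base_tr, level_m,
                                            out_dims = c(ncol(fimg),
                                                         nrow(fimg))))
      fit <- register(fimg, mimg, model = model, config = config,
                      seed = seeds[j])
      tr_base <- local_to_base_transform(fit$transform,
                                         c(tl$rect$x, tl$rect$y), f)
      status <- if (fit$status == "ok") "ok" else "failed"
      list(index = tl$index, rect = tl$rect,
           transform = if (status == "ok") tr_base
                       else identity_transform(rect_center(tl$rect)),
           status = status, metric = fit$metric)
    }, error = function(e) {
      list(index = tl$index, rect = tl$rect,
           transform = identity_transform(rect_center(tl$rect)),
           status = "failed", metric = NA_real_)
    })
    res[[length(res) + 1]] <- out
  }
  res
}

#' Strategy II: per-annotation patch correction
#'
#' Reads a small square patch centered on the annotation in the fixed slide
#' and the corresponding patch around the coarse-mapped coordinate in the
#' moving slide (with the inverse coarse rotation and scale applied to the
#' moving section), then registers the pair with an affine model. Patches
#' of 128 to 256 px work well; the default of 192 px sits in the middle of
#' that range. Annotations whose patch falls off either slide are flagged
#' and keep their coarse coordinate.
#'
#' @param p annotation as `c(x, y)` (base coordinates of the fixed slide).
#' @param base_tr coarse base transform.
#' @param fixed,moving `pyramid_image`s.
#' @param patch_size square patch side, 64..1024 px.
#' @param config refinement [reg_config()].
#' @param level_f,level_m resolution levels for the patch reads.
#' @param seed RNG seed.
#' @param id annotation id carried into the result.
#' @return A `point_correction`: `id`, `patch_size`, `transform` (base
#'   frame), `corrected` coordinate in moving base coordinates, `status`,
#'   `metric`.
#' @export
refine_point_strategy2 <- function(p, base_tr, fixed, moving,
                                   patch_size = 192,
                                   config = reg_config(n_resolutions = 1,
                                                       iterations = 250),
                                   level_f = 0, level_m = 0, seed = NULL,
                                   id = NA) {
  if (patch_size < 64 || patch_size > 1024)
    stop("patch_size must lie in [64, 1024]")
  p <- as.numeric(p)
  half <- patch_size / 2
  dims_f <- level_dims(fixed, 0)
  dims_m <- level_dims(moving, 0)
  coarse_q <- transform_point(base_tr, p)
  fail <- function(status) {
    structure(list(id = id, patch_size = patch_size, transform = NULL,
                   corrected = coarse_q, status = status, metric = NA_real_),
              class = "point_correction")
  }
  if (p[1] < half || p[2] < half ||
      p[1] > dims_f[1] - half || p[2] > dims_f[2] - half)
    return(fail("out_of_bounds"))
  rect <- wsi_rect(round(p[1]) - half, round(p[2]) - half,
                   patch_size, patch_size)
  mc <- transform_point(base_tr, rbind(
    c(rect$x, rect$y), c(rect$x + rect$w, rect$y),
    c(rect$x, rect$y + rect$h), c(rect$x + rect$w, rect$y + rect$h)))
  if (min(mc[, 1]) < 0 || min(mc[, 2]) < 0 ||
      max(mc[, 1]) > dims_m[1] || max(mc[, 2]) > dims_m[2])
    return(fail("out_of_bounds"))
  out <- tryCatch({
    f <- fixed$downsample_factors[level_f + 1]
    fimg <- to_gray(read_region(fixed, level_f, rect))
    mimg <- to_gray(extract_mapped_region(moving, rect, base_tr, level_m,
                                          out_dims = c(ncol(fimg),
                                                       nrow(fimg))))
    fit <- register(fimg, mimg, model = "affine", config = config, seed = seed)
    tr_base <- local_to_base_transform(fit$transform, c(rect$x, rect$y), f)
    corrected <- transform_point(base_tr, transform_point(tr_base, p))
    structure(list(id = id, patch_size = patch_size, transform = tr_base,
                   corrected = corrected, status = fit$status,
                   metric = fit$metric),
              class = "point_correction")
  }, error = function(e) fail("failed"))
  out
}

#' Recommend a refinement strategy for an annotation layout
#'
#' Compares the registered-pixel cost of tiling the occupied grid cells
#' (Strategy I) against per-annotation patches (Strategy II). Per-pixel
#' cost constants reflect that large-tile registration processes pixels
#' more cheaply than many small independent patch registrations. Purely
#' advisory.
#'
#' @param points data frame with `x`, `y`.
#' @param roi ROI [wsi_rect()].
#' @param tile_size Strategy I tile side (px).
#' @param patch_size Strategy II patch side (px).
#' @param cost_tile_px,cost_point_px relative per-pixel costs.
#' @return `list(recommendation, cost_strategy1, cost_strategy2)`.
#' @export
choose_strategy <- function(points, roi, tile_size = 2048, patch_size = 192,
                            cost_tile_px = 1, cost_point_px = 4) {
  stopifnot(nrow(points) >= 1)
  grid <- build_grid(roi, tile_size = tile_size, annotations = points)
  n_occ <- sum(grid$retained)
  cost1 <- count_registered_pixels(n_occ, tile_size) * cost_tile_px
  cost2 <- nrow(points) * patch_size^2 * cost_point_px
  list(recommendation = if (cost1 < cost2) "strategy1" else "strategy2",
       cost_strategy1 = cost1, cost_strategy2 = cost2)
}
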