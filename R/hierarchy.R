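# Coarse overview registration and its extrapolation to the base layer.
# Transforms carry explicit "estimated-at level" metadata; extrapolation is
# the single place where scale conversion between levels happens, which
# prevents silent double-scaling of parameters.

#' Coarse similarity registration of two slides on overview levels
#'
#' Crops the two ROIs at their respective overview levels (chosen per
#' magnification so both overviews have approximately matching mpp) and runs
#' a similarity registration with center initialization. The geometric
#' centers of the ROI crops serve as the rotation centers.
#'
#' @param fixed,moving `pyramid_image`s.
#' @param roi_f,roi_m ROI [wsi_rect()]s in base-layer coordinates (from
#'   segmentation or manual override).
#' @param levels optional `c(level_fixed, level_moving)`; defaults to
#'   [select_overview_level()] of each slide's magnification.
#' @param config a [reg_config()].
#' @param seed RNG seed.
#' @return A `coarse_result`: the overview-level transform plus everything
#'   needed to extrapolate it to the base layer.
#' @export
coarse_register <- function(fixed, moving, roi_f, roi_m, levels = NULL,
                            config = reg_config(), seed = NULL) {
  if (is.null(levels))
    levels <- c(select_overview_level(fixed$magnification, fixed),
                select_overview_level(moving$magnification, moving))
  lf <- levels[1]; lm <- levels[2]
  crop_f <- to_gray(read_region(fixed, lf, roi_f))
  crop_m <- to_gray(read_region(moving, lm, roi_m))
  fit <- register(crop_f, crop_m, model = "similarity", config = config,
                  seed = seed)
  structure(list(transform = fit$transform, metric = fit$metric,
                 status = fit$status, roi_f = roi_f, roi_m = roi_m,
                 level_f = lf, level_m = lm,
                 factor_f = fixed$downsample_factors[lf + 1],
                 factor_m = moving$downsample_factors[lm + 1]),
            class = "coarse_result")
}

#' @export
print.coarse_result <- function(x, ...) {
  cat(sprintf("<coarse registration  levels (%d, %d)  metric %.5f  status %s>\n",
              x$level_f, x$level_m, x$metric, x$status))
  print(x$transform)
  invisible(x)
}

#' Extrapolate a coarse overview transform to the base layer
#'
#' Rescales the overview-level similarity to base-layer coordinates (angle
#' and scale unchanged; translations and center multiplied by the level's
#' downsample factor) and composes it with the ROI-offset translations, so
#' that the result maps fixed base-layer coordinates directly into the
#' moving slide's base layer.
#'
#' @param cr a `coarse_result`.
#' @return A base-layer `similarity_transform`.
#' @export
extrapolate_to_base <- function(cr) {
  stopifnot(inherits(cr, "coarse_result"))
  tr <- cr$transform
  o_f <- c(cr$roi_f$x, cr$roi_f$y)
  o_m <- c(cr$roi_m$x, cr$roi_m$y)
  ff <- cr$factor_f; fm <- cr$factor_m
  c_ov <- tr$center
  c_base <- o_f + ff * c_ov
  s_base <- tr$scale * fm / ff
  t_base <- fm * (c_ov + c(tr$tx, tr$ty)) + o_m - c_base
  similarity_transform(tr$angle, s_base, t_base[1], t_base[2], c_base)
}

#' Extract a rotated region from a pyramid level
#'
#' Retrieves the axis-aligned bounding box of `rect` rotated by `theta`
#' about `center`, compensates the rotation with cubic interpolation and
#' crops centrally back to `rect`'s dimensions — the procedure needed
#' because slide readers only serve axis-aligned tiles.
#'
#' @param pyr a `pyramid_image`.
#' @param rect a [wsi_rect()] in base-layer coordinates (the region's
#'   dimensions define the output size, divided by the level factor).
#' @param theta rotation angle in degrees (package angle convention).
#' @param center rotation center in base coordinates; defaults to the
#'   rect's geometric center.
#' @param level pyramid level to read.
#' @param background fill for out-of-slide area.
#' @return The region array with attribute `clipped`.
#' @export
extract_rotated_region <- function(pyr, rect, theta, center = rect_center(rect),
                                   level = 0, background = 255) {
  tr <- similarity_transform(theta, 1, 0, 0, center)
  extract_mapped_region(pyr, rect, tr, level = level, background = background)
}

# Extract the image region corresponding to `rect` (fixed frame) mapped
# through `tr` (fixed -> this pyramid's frame): output pixel u equals the
# pyramid sampled at tr(rect_origin + u * fs). This is the general form of
# the rotated-bounding-box extraction, additionally compensating scale.
# out_dims overrides the output size (used when fixed and moving slides are
# read at different levels of matched mpp).
extract_mapped_region <- function(pyr, rect, tr, level = 0, background = 255,
                                  out_dims = NULL) {
  f <- pyr$downsample_factors[level + 1]
  if (is.null(out_dims))
    out_dims <- c(max(1, round(rect$w / f)), max(1, round(rect$h / f)))
  ow <- out_dims[1]; oh <- out_dims[2]
  corners <- rbind(c(rect$x, rect$y),
                   c(rect$x + rect$w, rect$y),
                   c(rect$x, rect$y + rect$h),
                   c(rect$x + rect$w, rect$y + rect$h))
  mc <- transform_point(tr, corners)
  pad <- 3 * f
  bx0 <- floor(min(mc[, 1])) - pad; by0 <- floor(min(mc[, 2])) - pad
  bx1 <- ceiling(max(mc[, 1])) + pad; by1 <- ceiling(max(mc[, 2])) + pad
  dims <- level_dims(pyr, 0)
  if (bx1 <= 0 || by1 <= 0 || bx0 >= dims[1] || by0 >= dims[2])
    stop("mapped region lies entirely outside the slide")
  bbox <- wsi_rect(bx0, by0, bx1 - bx0, by1 - by0)
  sub <- read_region(pyr, level, bbox, background = background)
  clipped <- attr(sub, "clipped")
  g <- grid_coords(ow, oh)
  fx <- rect$w / ow; fy <- rect$h / oh
  p_base <- cbind(rect$x + g[, 1] * fx, rect$y + g[, 2] * fy)
  q_base <- transform_point(tr, p_base)
  # local coordinates inside the bounding-box read at this level
  qx <- (q_base[, 1] - round(bx0 / f) * f) / f
  qy <- (q_base[, 2] - round(by0 / f) * f) / f
  one <- function(ch) {
    matrix(cpp_interp(cpp_bspline_prefilter(ch), qx, qy, 3L, background),
           oh, ow)
  }
  out <- if (length(dim(sub)) == 3) {
    chs <- lapply(1:3, function(k) one(sub[, , k]))
    array(c(chs[[1]], chs[[2]], chs[[3]]), c(oh, ow, 3))
  } else one(sub)
  attr(out, "clipped") <- clipped
  out
}

#' Write a diagnostic overlay of the coarse pre-registration
#'
#' Renders the fixed ROI overview in the red channel and the moving ROI
#' overview, warped by the coarse transform, in the green channel; aligned
#' tissue appears yellow. Intended for the manual visual inspection that
#' heterogeneous slide pairs occasionally need.
#'
#' @param path output PNG path.
#' @param cr a `coarse_result`.
#' @param fixed,moving the registered `pyramid_image`s.
#' @export
write_overlay_png <- function(path, cr, fixed, moving) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for overlay export")
  crop_f <- to_gray(read_region(fixed, cr$level_f, cr$roi_f))
  crop_m <- to_gray(read_region(moving, cr$level_m, cr$roi_m))
  warped <- resample_image(crop_m, cr$transform, order = 1,
                           out_dims = c(ncol(crop_f), nrow(crop_f)))
  arr <- array(0, c(dim(crop_f), 3))
  arr[, , 1] <- 1 - crop_f / 255
  arr[, , 2] <- 1 - warped / 255
  png::writePNG(arr, path)
  invisible(path)
}
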