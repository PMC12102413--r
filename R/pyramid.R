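#' Pyramidal whole-slide image container
#'
#' Holds an ordered list of resolution levels (level 0 = base layer, the
#' full-resolution scan), per-level downsample factors, and physical
#' metadata: micrometers per pixel (mpp) at the base layer and the nominal
#' scan magnification.
#'
#' Grayscale levels are `h x w` matrices, RGB levels `h x w x 3` arrays, with
#' intensities on the 0..255 scale. Matrix rows are y, columns x.
#'
#' @param levels list of level arrays, base layer first.
#' @param downsample_factors per-level positive factors relative to the base
#'   layer; default powers of two.
#' @param mpp_x,mpp_y micrometers per pixel at the base layer.
#' @param magnification nominal scan magnification (e.g. 40, 80).
#' @param orientation one of `"none"`, `"rot90"`, `"rot180"`, `"rot270"`,
#'   `"flip_h"`, `"flip_v"`, `"transpose"`, `"anti_transpose"` — the
#'   orientation of the stored data relative to its reference presentation.
#' @return An object of class `pyramid_image`.
#' @export
pyramid_image <- function(levels, downsample_factors = 2^(seq_along(levels) - 1),
                          mpp_x, mpp_y = mpp_x, magnification = 40,
                          orientation = "none") {
  stopifnot(is.list(levels), length(levels) >= 1)
  if (mpp_x <= 0 || mpp_y <= 0) stop("mpp must be positive")
  if (magnification <= 0) stop("magnification must be positive")
  orientation <- match.arg(orientation, orientation_ops())
  if (length(downsample_factors) != length(levels))
    stop("one downsample factor per level required")
  if (any(downsample_factors <= 0)) stop("downsample factors must be positive")
  default_factors <- isTRUE(all.equal(downsample_factors,
                                      2^(seq_along(levels) - 1)))
  if (default_factors && length(levels) > 1) {
    for (k in 2:length(levels)) {
      d0 <- dim(levels[[k - 1]])[1:2]
      dk <- dim(levels[[k]])[1:2]
      if (!all(dk == ceiling(d0 / 2)))
        stop("level ", k - 1, " dimensions must be ceiling(previous / 2)")
    }
  }
  structure(list(levels = levels, downsample_factors = downsample_factors,
                 mpp_x = mpp_x, mpp_y = mpp_y, magnification = magnification,
                 orientation = orientation),
            class = "pyramid_image")
}

#' @export
print.pyramid_image <- function(x, ...) {
  d <- dim(x$levels[[1]])
  cat(sprintf("<pyramid image  %d x %d base, %d level(s), %.4f mpp, %gx>\n",
              d[2], d[1], length(x$levels), x$mpp_x, x$magnification))
  invisible(x)
}

n_levels <- function(pyr) length(pyr$levels)

# (w, h) of a level
level_dims <- function(pyr, level) {
  d <- dim(pyr$levels[[level + 1]])
  c(d[2], d[1])
}

pyr_is_rgb <- function(pyr) length(dim(pyr$levels[[1]])) == 3

#' Convert an RGB array to luminance
#'
#' Rec. 601 luminance; grayscale inputs pass through unchanged.
#' @param img `h x w` matrix or `h x w x 3` array, 0..255.
#' @export
to_gray <- function(img) {
  if (length(dim(img)) == 2) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Select the overview level for coarse registration
#'
#' Picks the pyramid level whose effective magnification is closest to 2.5x:
#' a slide scanned at 80x uses level 5 (downsampling 2^5), one at 40x level 4,
#' one at 20x level 3. The result is clamped to the available levels when a
#' pyramid is supplied.
#'
#' @param magnification nominal scan magnification (> 0).
#' @param pyr optional `pyramid_image` used to clamp the level.
#' @return Integer level index (0 = base layer).
#' @export
select_overview_level <- function(magnification, pyr = NULL) {
  if (!is.numeric(magnification) || magnification <= 0)
    stop("magnification must be positive")
  lev <- max(0L, as.integer(round(log2(magnification / 2.5))))
  if (!is.null(pyr)) lev <- min(lev, n_levels(pyr) - 1L)
  lev
}

#' Convert physical distances to pixels
#'
#' @param distance distance in micrometers.
#' @param mpp micrometers per pixel (> 0).
#' @return Distance in pixels (`distance / mpp`).
#' @export
microns_to_pixels <- function(distance, mpp) {
  if (any(mpp <= 0)) stop("mpp must be positive")
  distance / mpp
}

#' Relative apparent size difference between two scan resolutions
#'
#' Structures on the slide with the coarser resolution (larger mpp) appear
#' larger when both scans are rendered at equal pixel counts; this returns
#' that difference as a percentage, `100 * (mpp_a / mpp_b - 1)`.
#'
#' @param mpp_a,mpp_b micrometers per pixel of the two scans.
#' @export
relative_scale_percent <- function(mpp_a, mpp_b) {
  if (any(c(mpp_a, mpp_b) <= 0)) stop("mpp values must be positive")
  100 * (mpp_a / mpp_b - 1)
}

#' Build an image pyramid from a base array
#'
#' Each level is the 2x decimation of the previous one after Gaussian
#' anti-alias filtering (sigma = 2/3 per halving); level dimensions follow
#' `ceiling(previous / 2)`.
#'
#' @param base `h x w` matrix or `h x w x 3` array (0..255).
#' @param n_levels number of levels including the base (>= 1).
#' @param mpp base-layer micrometers per pixel.
#' @param magnification nominal magnification.
#' @param orientation stored orientation tag.
#' @return A [pyramid_image()].
#' @export
build_pyramid <- function(base, n_levels, mpp, magnification = 40,
                          orientation = "none") {
  stopifnot(n_levels >= 1)
  d <- dim(base)[1:2]
  if (n_levels - 1 > floor(log2(min(d))))
    stop("n_levels exceeds log2 of the smallest base dimension")
  halve <- function(img) {
    sm <- cpp_gauss_blur(img, 2 / 3)
    sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2), drop = FALSE]
  }
  halve_any <- function(img) {
    if (length(dim(img)) == 3) {
      ch <- lapply(1:3, function(k) halve(img[, , k]))
      array(c(ch[[1]], ch[[2]], ch[[3]]), dim = c(dim(ch[[1]]), 3))
    } else halve(img)
  }
  levels <- vector("list", n_levels)
  levels[[1]] <- base
  if (n_levels > 1)
    for (k in 2:n_levels) levels[[k]] <- halve_any(levels[[k - 1]])
  pyramid_image(levels, mpp_x = mpp, magnification = magnification,
                orientation = orientation)
}

#' Read a region from a pyramid level
#'
#' `rect` is given in base-layer coordinates and divided by the level's
#' downsample factor before reading. Area outside the image is filled with
#' `background` and flagged.
#'
#' @param pyr a `pyramid_image`.
#' @param level level index (0-based).
#' @param rect a [wsi_rect()] in base-layer coordinates.
#' @param background fill value for out-of-bounds area (default 255, white
#'   slide background).
#' @return The region array, with attribute `clipped` set to `TRUE` when part
#'   of the request fell outside the image.
#' @export
read_region <- function(pyr, level, rect, background = 255) {
  stopifnot(inherits(pyr, "pyramid_image"), inherits(rect, "wsi_rect"))
  if (level < 0 || level >= n_levels(pyr)) stop("no such pyramid level")
  f <- pyr$downsample_factors[level + 1]
  lx <- round(rect$x / f); ly <- round(rect$y / f)
  lw <- max(1, round(rect$w / f)); lh <- max(1, round(rect$h / f))
  arr <- pyr$levels[[level + 1]]
  d <- dim(arr)
  W <- d[2]; H <- d[1]
  x0 <- max(lx, 0); y0 <- max(ly, 0)
  x1 <- min(lx + lw, W); y1 <- min(ly + lh, H)
  if (x1 <= x0 || y1 <= y0)
    stop("requested region does not intersect the image")
  rgb <- length(d) == 3
  out <- if (rgb) array(background, c(lh, lw, 3)) else
    matrix(background, lh, lw)
  rows <- (y0 + 1):y1; cols <- (x0 + 1):x1
  orow <- rows - ly; ocol <- cols - lx
  if (rgb) out[orow, ocol, ] <- arr[rows, cols, , drop = FALSE]
  else out[orow, ocol] <- arr[rows, cols, drop = FALSE]
  clipped <- (x0 != lx) || (y0 != ly) || (x1 != lx + lw) || (y1 != ly + lh)
  attr(out, "clipped") <- clipped
  out
}

# ---- plain pyramidal TIFF + JSON sidecar -----------------------------------

#' Write / read a pyramid as a multi-page TIFF with a JSON metadata sidecar
#'
#' One TIFF page per level; mpp, magnification, orientation and downsample
#' factors go to `<path>.json`. Only plain (non-proprietary) TIFF is handled;
#' vendor formats are out of scope and can be adapted through this interface.
#'
#' @param pyr a `pyramid_image`.
#' @param path output TIFF path.
#' @export
write_pyramid_tiff <- function(pyr, path) {
  pages <- lapply(pyr$levels, function(a) pmin(pmax(round(a), 0), 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(mpp_x = pyr$mpp_x, mpp_y = pyr$mpp_y,
               magnification = pyr$magnification,
               orientation = pyr$orientation,
               downsample_factors = pyr$downsample_factors)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pyramid_tiff
#' @export
read_pyramid_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  levels <- lapply(pages, function(a) {
    if (length(dim(a)) == 3 && dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
    a * 255
  })
  pyramid_image(levels, downsample_factors = meta$downsample_factors,
                mpp_x = meta$mpp_x, mpp_y = meta$mpp_y,
                magnification = meta$magnification,
                orientation = meta$orientation)
}

#' Read / write point annotations
#'
#' CSV with columns `x,y[,label]` or a JSON list of `{x, y}` objects; all
#' coordinates are base-layer pixels.
#'
#' @param path file path (`.csv` or `.json`).
#' @export
read_points <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(df)
  } else {
    df <- read.csv(path)
  }
  stopifnot(all(c("x", "y") %in% names(df)))
  df
}

#' @rdname read_points
#' @param points data frame with columns `x`, `y` and optionally `label`.
#' @export
write_points <- function(points, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(points, path, dataframe = "rows", digits = NA)
  } else {
    write.csv(points, path, row.names = FALSE)
  }
  invisible(path)
}
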