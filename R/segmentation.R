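# Tissue pre-segmentation on overview images. The scanned area can differ
# substantially between scanners, so registration is restricted to a tight
# ROI around the relevant tissue, found by Otsu thresholding plus morphology
# and a particle-relevance filter; a manual override replaces the automatic
# ROI when the naive segmentation fails.

#' Segment tissue on an overview image
#'
#' Otsu-thresholds the (luminance) overview under the dark-tissue-on-light-
#' background convention, then applies dilation, erosion and hole filling
#' with a disc structuring element.
#'
#' @param overview `h x w` matrix or `h x w x 3` array (0..255).
#' @param brush_radius disc radius (px) for dilation and erosion.
#' @return Logical `h x w` mask with attribute `failure` (`TRUE` when the
#'   histogram is degenerate, e.g. a constant image; the mask is then empty).
#' @export
segment_tissue <- function(overview, brush_radius = 3) {
  gray <- to_gray(overview)
  if (diff(range(gray)) < .Machine$double.eps * 255) {
    mask <- matrix(FALSE, nrow(gray), ncol(gray))
    attr(mask, "failure") <- TRUE
    warning("degenerate intensity histogram; segmentation failed")
    return(mask)
  }
  eb <- EBImage::Image(t(gray) / 255)
  th <- EBImage::otsu(eb, range = c(0, 1), levels = 256)
  bin <- EBImage::Image(t(gray / 255 < th))
  brush <- EBImage::makeBrush(2 * brush_radius + 1, shape = "disc")
  bin <- EBImage::erode(EBImage::dilate(bin, brush), brush)
  bin <- EBImage::fillHull(bin)
  mask <- t(EBImage::imageData(bin)) > 0.5
  attr(mask, "failure") <- FALSE
  mask
}

#' Connected tissue particles of a segmentation mask
#'
#' Labels connected components and records per-particle area, centroid and
#' bounding rectangle, all in overview coordinates, together with the factor
#' mapping overview to base-layer coordinates.
#'
#' @param mask logical overview mask.
#' @param factor overview-to-base downsample factor.
#' @param base_dims base-layer dimensions `c(W, H)`; defaults to the mask
#'   dimensions times `factor`.
#' @return A `particle_set`.
#' @export
label_particles <- function(mask, factor = 1,
                            base_dims = c(ncol(mask), nrow(mask)) * factor) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
  n <- max(lab)
  if (n == 0) {
    df <- data.frame(id = integer(), area = numeric(), cx = numeric(),
                     cy = numeric(), x0 = numeric(), y0 = numeric(),
                     w = numeric(), h = numeric())
  } else {
    idx <- which(lab > 0, arr.ind = TRUE)
    id <- lab[lab > 0]
    xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
    area <- tabulate(id, n)
    cx <- rowsum(xs, id)[, 1] / area
    cy <- rowsum(ys, id)[, 1] / area
    x0 <- tapply(xs, id, min); x1 <- tapply(xs, id, max)
    y0 <- tapply(ys, id, min); y1 <- tapply(ys, id, max)
    df <- data.frame(id = seq_len(n), area = area, cx = cx, cy = cy,
                     x0 = as.numeric(x0), y0 = as.numeric(y0),
                     w = as.numeric(x1 - x0 + 1), h = as.numeric(y1 - y0 + 1))
  }
  structure(list(particles = df, labels = lab, factor = factor,
                 base_dims = base_dims),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle set: %d particle(s), overview->base factor %g>\n",
              nrow(x$particles), x$factor))
  invisible(x)
}

#' Filter tissue particles by relevance
#'
#' Keeps particles whose area is at least `mean(area) - k_a * sd(area)` and
#' whose centroid lies within `mean(d) + k_d * sd(d)` of the (by default
#' area-weighted) mass center of all particles, where `d` are the centroid
#' distances from that mass center. The rule is iterated to a fixed point so
#' that filtering is idempotent. If every particle would be removed, the
#' largest one is kept and a warning is issued — downstream registration
#' always needs an ROI.
#'
#' @param ps a `particle_set`.
#' @param k_a,k_d multipliers of the area and distance standard deviations.
#' @param weighted use the area-weighted mass center (default) or unweighted.
#' @return The filtered `particle_set`.
#' @export
filter_particles <- function(ps, k_a = 1, k_d = 1, weighted = TRUE) {
  stopifnot(inherits(ps, "particle_set"))
  df <- ps$particles
  if (nrow(df) == 0) stop("particle set is empty")
  full <- df
  repeat {
    if (nrow(df) <= 1) break
    a <- df$area
    sa <- sd(a)
    keep_a <- a >= mean(a) - k_a * sa
    wgt <- if (weighted) a else rep(1, length(a))
    mc <- c(sum(df$cx * wgt), sum(df$cy * wgt)) / sum(wgt)
    d <- sqrt((df$cx - mc[1])^2 + (df$cy - mc[2])^2)
    sdd <- sd(d)
    keep_d <- d <= mean(d) + k_d * sdd
    keep <- keep_a & keep_d
    if (all(keep)) break
    if (!any(keep)) {
      df <- df[which.max(df$area), , drop = FALSE]
      warning("all particles failed the relevance filter; keeping the largest")
      break
    }
    df <- df[keep, , drop = FALSE]
  }
  lab <- ps$labels
  lab[!(lab %in% df$id)] <- 0
  structure(list(particles = df, labels = lab, factor = ps$factor,
                 base_dims = ps$base_dims),
            class = "particle_set")
}

#' Tight ROI around the kept particles
#'
#' Union bounding box of all particles, expanded by `margin` on each side,
#' clipped to the slide bounds, returned in base-layer coordinates.
#'
#' @param ps a `particle_set`.
#' @param margin expansion in base-layer pixels.
#' @return A [wsi_rect()] in base-layer coordinates.
#' @export
roi_from_particles <- function(ps, margin = 0) {
  df <- ps$particles
  if (nrow(df) == 0) stop("particle set is empty")
  f <- ps$factor
  x0 <- min(df$x0) * f - margin
  y0 <- min(df$y0) * f - margin
  x1 <- (max(df$x0 + df$w)) * f + margin
  y1 <- (max(df$y0 + df$h)) * f + margin
  x0 <- max(0, x0); y0 <- max(0, y0)
  x1 <- min(ps$base_dims[1], x1); y1 <- min(ps$base_dims[2], y1)
  wsi_rect(x0, y0, x1 - x0, y1 - y0)
}

#' Manually override an automatic ROI
#'
#' Replaces the automatic ROI verbatim after a bounds check; the override is
#' reported so that it appears in run logs.
#'
#' @param manual a [wsi_rect()] in base-layer coordinates.
#' @param slide_dims slide base dimensions `c(W, H)`.
#' @export
override_roi <- function(manual, slide_dims) {
  stopifnot(inherits(manual, "wsi_rect"))
  if (manual$x < 0 || manual$y < 0 ||
      manual$x + manual$w > slide_dims[1] ||
      manual$y + manual$h > slide_dims[2])
    stop("manual ROI lies outside the slide bounds")
  message(sprintf("ROI manually overridden: %g x %g at (%g, %g)",
                  manual$w, manual$h, manual$x, manual$y))
  manual
}

# full overview segmentation -> filtered particles -> base-coordinate ROI
auto_roi <- function(pyr, level = select_overview_level(pyr$magnification, pyr),
                     margin = 0, k_a = 1, k_d = 1) {
  f <- pyr$downsample_factors[level + 1]
  ov <- pyr$levels[[level + 1]]
  mask <- segment_tissue(ov)
  if (isTRUE(attr(mask, "failure")))
    stop("tissue segmentation failed; supply a manual ROI")
  d0 <- level_dims(pyr, 0)
  ps <- filter_particles(label_particles(mask, f, d0), k_a = k_a, k_d = k_d)
  roi_from_particles(ps, margin = margin)
}
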