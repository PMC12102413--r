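#' Axis-aligned rectangle in base-layer pixel coordinates
#'
#' Rectangles are half-open: they cover `[x, x + w) x [y, y + h)` in the
#' 0-based pixel frame (x = column increasing rightward, y = row increasing
#' downward; pixel centers at integer coordinates).
#'
#' @param x,y top-left corner (base-layer pixels, 0-based).
#' @param w,h extent in pixels; must be positive.
#' @return An object of class `wsi_rect`.
#' @export
wsi_rect <- function(x, y, w, h) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(w), is.numeric(h))
  if (w <= 0 || h <= 0) stop("rectangle extents must be positive")
  structure(list(x = x, y = y, w = w, h = h), class = "wsi_rect")
}

#' @export
print.wsi_rect <- function(x, ...) {
  cat(sprintf("<rect %g x %g at (%g, %g)>\n", x$w, x$h, x$x, x$y))
  invisible(x)
}

rect_center <- function(r) c(r$x + (r$w - 1) / 2, r$y + (r$h - 1) / 2)

rect_intersect <- function(a, b) {
  x0 <- max(a$x, b$x); y0 <- max(a$y, b$y)
  x1 <- min(a$x + a$w, b$x + b$w); y1 <- min(a$y + a$h, b$y + b$h)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  wsi_rect(x0, y0, x1 - x0, y1 - y0)
}

rect_contains_point <- function(r, p) {
  p[1] >= r$x & p[1] < r$x + r$w & p[2] >= r$y & p[2] < r$y + r$h
}

# ---- parametric 2-D transforms ---------------------------------------------
#
# Angle convention (used everywhere in the package): degrees, counter-
# clockwise positive in the y-down pixel frame, i.e. the rotation matrix is
#   R(theta) = [  cos  sin ]
#              [ -sin  cos ]
# so that R(90) maps (1, 0) to (0, -1). All transforms map fixed-domain
# coordinates into the moving domain as p -> s R (p - c) + c + t (similarity)
# or p -> A (p - c) + c + t (affine), with an explicit rotation center c.

rot_mat <- function(angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
}

#' Parametric 2-D transforms with an explicit rotation center
#'
#' A similarity transform maps `p -> s * R(angle) %*% (p - c) + c + t`; it has
#' four free parameters (angle, isotropic scale, tx, ty) plus a fixed center.
#' A rigid transform is the special case `scale = 1`; an affine transform
#' replaces `s * R` with an arbitrary non-singular 2x2 matrix.
#'
#' Angles are in degrees, counter-clockwise positive in the y-down pixel
#' frame (so +90 degrees maps (1, 0) to (0, -1)).
#'
#' @param angle rotation in degrees.
#' @param scale isotropic scale factor (> 0).
#' @param tx,ty translation in pixels.
#' @param center rotation center `c(cx, cy)` in pixels.
#' @return An object of class `wsi_transform`.
#' @export
similarity_transform <- function(angle = 0, scale = 1, tx = 0, ty = 0,
                                 center = c(0, 0)) {
  if (scale <= 0) stop("scale must be positive")
  structure(list(angle = angle, scale = scale, tx = tx, ty = ty,
                 center = as.numeric(center)),
            class = c("similarity_transform", "wsi_transform"))
}

#' @rdname similarity_transform
#' @export
rigid_transform <- function(angle = 0, tx = 0, ty = 0, center = c(0, 0)) {
  out <- similarity_transform(angle, 1, tx, ty, center)
  class(out) <- c("rigid_transform", class(out))
  out
}

#' @rdname similarity_transform
#' @param A 2x2 linear part (affine only); must be non-singular.
#' @export
affine_transform <- function(A = diag(2), tx = 0, ty = 0, center = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < .Machine$double.eps) stop("affine matrix must be non-singular")
  structure(list(A = A, tx = tx, ty = ty, center = as.numeric(center)),
            class = c("affine_transform", "wsi_transform"))
}

#' @rdname similarity_transform
#' @export
identity_transform <- function(center = c(0, 0)) similarity_transform(center = center)

linear_part <- function(tr) {
  if (inherits(tr, "affine_transform")) tr$A else tr$scale * rot_mat(tr$angle)
}

# matrix form: p -> M p + b (center absorbed)
transform_matrix_form <- function(tr) {
  M <- linear_part(tr)
  c0 <- tr$center
  b <- c0 + c(tr$tx, tr$ty) - M %*% c0
  list(M = M, b = as.numeric(b))
}

# rebuild a transform from matrix form, keeping a stated center
transform_from_matrix <- function(M, b, center = c(0, 0), similarity = NULL) {
  sim <- similarity %||% {
    s2 <- det(M)
    s2 > 0 && abs(M[1, 1] - M[2, 2]) < 1e-9 * max(1, abs(M[1, 1])) &&
      abs(M[1, 2] + M[2, 1]) < 1e-9 * max(1, abs(M[1, 2]))
  }
  t0 <- as.numeric(b + M %*% center - center)
  if (isTRUE(sim)) {
    s <- sqrt(det(M))
    ang <- atan2(M[1, 2], M[1, 1]) * 180 / pi
    similarity_transform(ang, s, t0[1], t0[2], center)
  } else {
    affine_transform(M, t0[1], t0[2], center)
  }
}

#' Apply a transform to points
#'
#' Maps points from the fixed domain into the moving domain. Points may be a
#' length-2 vector or an n x 2 matrix / data frame with columns (x, y).
#'
#' @param tr a `wsi_transform`.
#' @param p points.
#' @return Points in the same shape as the input.
#' @export
transform_point <- function(tr, p) {
  stopifnot(inherits(tr, "wsi_transform"))
  vec <- is.null(dim(p))
  pm <- if (vec) matrix(as.numeric(p), 1, 2) else as.matrix(p)[, 1:2, drop = FALSE]
  M <- linear_part(tr)
  c0 <- tr$center
  out <- sweep(pm, 2, c0) %*% t(M)
  out <- sweep(out, 2, c0 + c(tr$tx, tr$ty), `+`)
  if (vec) as.numeric(out) else out
}

#' Invert a transform
#' @param tr a `wsi_transform`.
#' @return The inverse transform (same center, same family).
#' @export
invert_transform <- function(tr) {
  mf <- transform_matrix_form(tr)
  Mi <- solve(mf$M)
  bi <- as.numeric(-Mi %*% mf$b)
  transform_from_matrix(Mi, bi, tr$center,
                        similarity = !inherits(tr, "affine_transform"))
}

#' Compose two transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#' The composition of two similarities is a similarity; otherwise affine.
#'
#' @param second,first `wsi_transform`s.
#' @param center rotation center of the result (default: `first`'s center).
#' @export
compose_transforms <- function(second, first, center = first$center) {
  m1 <- transform_matrix_form(first)
  m2 <- transform_matrix_form(second)
  M <- m2$M %*% m1$M
  b <- as.numeric(m2$M %*% m1$b + m2$b)
  both_sim <- !inherits(first, "affine_transform") &&
    !inherits(second, "affine_transform")
  transform_from_matrix(M, b, center, similarity = both_sim)
}

#' @export
print.wsi_transform <- function(x, ...) {
  if (inherits(x, "affine_transform")) {
    cat(sprintf("<affine transform  A = [%.4f %.4f; %.4f %.4f]  t = (%.3f, %.3f)  c = (%.1f, %.1f)>\n",
                x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$tx, x$ty,
                x$center[1], x$center[2]))
  } else {
    cat(sprintf("<similarity transform  angle = %.4f deg  scale = %.5f  t = (%.3f, %.3f)  c = (%.1f, %.1f)>\n",
                x$angle, x$scale, x$tx, x$ty, x$center[1], x$center[2]))
  }
  invisible(x)
}

# serialize / restore transforms (full double precision via base::format)
transform_to_list <- function(tr) {
  if (inherits(tr, "affine_transform")) {
    list(type = "affine", A = as.numeric(tr$A), tx = tr$tx, ty = tr$ty,
         center = tr$center)
  } else {
    list(type = if (inherits(tr, "rigid_transform")) "rigid" else "similarity",
         angle = tr$angle, scale = tr$scale, tx = tr$tx, ty = tr$ty,
         center = tr$center)
  }
}

transform_from_list <- function(x) {
  switch(x$type,
    affine = affine_transform(matrix(unlist(x$A), 2, 2), x$tx, x$ty,
                              unlist(x$center)),
    rigid = rigid_transform(x$angle, x$tx, x$ty, unlist(x$center)),
    similarity = similarity_transform(x$angle, x$scale, x$tx, x$ty,
                                      unlist(x$center)),
    stop("unknown transform type: ", x$type))
}
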