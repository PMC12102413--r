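# Orientation pre-transforms: the eight axis-aligned flips/rotations that a
# scanner may introduce. These are exact integer coordinate remaps; they are
# configured as runtime parameters because right-angle rotations and mirrored
# scans are impractical to detect automatically.

orientation_ops <- function() {
  c("none", "rot90", "rot180", "rot270", "flip_h", "flip_v",
    "transpose", "anti_transpose")
}

# rot90 is a 90-degree clockwise rotation of the displayed image.
# Linear parts of the eight ops in the (x, y) row-vector convention.
orientation_matrix <- function(op) {
  switch(op,
    none = diag(2),
    rot90 = matrix(c(0, 1, -1, 0), 2, 2),
    rot180 = -diag(2),
    rot270 = matrix(c(0, -1, 1, 0), 2, 2),
    flip_h = diag(c(-1, 1)),
    flip_v = diag(c(1, -1)),
    transpose = matrix(c(0, 1, 1, 0), 2, 2),
    anti_transpose = matrix(c(0, -1, -1, 0), 2, 2),
    stop("unknown orientation op: ", op))
}

orientation_swaps_axes <- function(op) {
  op %in% c("rot90", "rot270", "transpose", "anti_transpose")
}

#' @rdname apply_orientation_pretransform
#' @export
orientation_inverse <- function(op) {
  switch(op, rot90 = "rot270", rot270 = "rot90", op)
}

#' @rdname apply_orientation_pretransform
#' @param op2,op1 operation names; the result is "op1 then op2".
#' @export
orientation_compose <- function(op2, op1) {
  M <- orientation_matrix(op2) %*% orientation_matrix(op1)
  for (op in orientation_ops())
    if (all(M == orientation_matrix(op))) return(op)
  stop("composition fell outside the dihedral group")  # unreachable
}

#' Apply an orientation pre-transform to points or an image
#'
#' The eight dihedral operations (identity, right-angle rotations, flips,
#' transposes) as exact coordinate remaps. `rot90` rotates the displayed
#' image 90 degrees clockwise; `flip_h` mirrors x (`x -> W - 1 - x`).
#' For points, `dims = c(W, H)` are the dimensions of the *source* frame.
#'
#' @param x an `n x 2` point matrix / data frame, a length-2 point, or an
#'   image array (`h x w` or `h x w x 3`).
#' @param op one of the eight operation names (see `orientation_ops`).
#' @param dims source frame dimensions `c(W, H)`; taken from the array when
#'   `x` is an image.
#' @return Transformed points (same shape) or the transformed image.
#' @export
apply_orientation_pretransform <- function(x, op, dims = NULL) {
  op <- match.arg(op, orientation_ops())
  if (is.array(x) && length(dim(x)) >= 2 && (is.null(dims))) {
    return(orient_image(x, op))
  }
  if (is.null(dims)) stop("dims = c(W, H) required for point input")
  vec <- is.null(dim(x))
  pm <- if (vec) matrix(as.numeric(x), 1, 2) else as.matrix(x)[, 1:2, drop = FALSE]
  W <- dims[1]; H <- dims[2]
  out <- switch(op,
    none = pm,
    rot90 = cbind(H - 1 - pm[, 2], pm[, 1]),
    rot180 = cbind(W - 1 - pm[, 1], H - 1 - pm[, 2]),
    rot270 = cbind(pm[, 2], W - 1 - pm[, 1]),
    flip_h = cbind(W - 1 - pm[, 1], pm[, 2]),
    flip_v = cbind(pm[, 1], H - 1 - pm[, 2]),
    transpose = pm[, 2:1, drop = FALSE],
    anti_transpose = cbind(H - 1 - pm[, 2], W - 1 - pm[, 1]))
  if (vec) as.numeric(out) else out
}

orient_matrix2d <- function(m, op) {
  switch(op,
    none = m,
    rot90 = t(m)[, nrow(m):1, drop = FALSE],
    rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot270 = t(m)[ncol(m):1, , drop = FALSE],
    flip_h = m[, ncol(m):1, drop = FALSE],
    flip_v = m[nrow(m):1, , drop = FALSE],
    transpose = t(m),
    anti_transpose = t(m)[ncol(m):1, nrow(m):1, drop = FALSE])
}

orient_image <- function(img, op) {
  if (length(dim(img)) == 3) {
    ch <- lapply(seq_len(dim(img)[3]), function(k) orient_matrix2d(img[, , k], op))
    array(unlist(ch), dim = c(dim(ch[[1]]), length(ch)))
  } else orient_matrix2d(img, op)
}

# Re-orient a whole pyramid (used to harmonize the moving slide before
# registration; the inverse op is appended to the transform chain).
orient_pyramid <- function(pyr, op) {
  if (op == "none") return(pyr)
  levels <- lapply(pyr$levels, orient_image, op = op)
  pyramid_image(levels, downsample_factors = pyr$downsample_factors,
                mpp_x = pyr$mpp_x, mpp_y = pyr$mpp_y,
                magnification = pyr$magnification, orientation = "none")
}
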