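# Multi-resolution parametric registration driver. Transform parameters are
# always expressed in the full-resolution frame of the two input images;
# each resolution level evaluates the metric on its own downsampled pair by
# scaling sample coordinates, so no parameter rescaling between levels is
# needed. Heterogeneous parameters (degrees, scale, pixels) are optimized in
# a scaled space where one unit of any parameter induces about one pixel of
# motion at the image corner.

model_names <- function() c("similarity", "rigid", "affine")

param_scales <- function(model, radius) {
  switch(model,
    rigid = c((180 / pi) / radius, 1, 1),
    similarity = c((180 / pi) / radius, 1 / radius, 1, 1),
    affine = c(rep(1 / radius, 4), 1, 1))
}

params_from_transform <- function(model, tr) {
  switch(model,
    rigid = c(tr$angle, tr$tx, tr$ty),
    similarity = c(tr$angle, tr$scale, tr$tx, tr$ty),
    affine = {
      A <- linear_part(tr)
      c(A[1, 1], A[1, 2], A[2, 1], A[2, 2], tr$tx, tr$ty)
    })
}

params_to_transform <- function(model, x, center) {
  switch(model,
    rigid = rigid_transform(x[1], x[2], x[3], center),
    similarity = similarity_transform(x[1], max(x[2], 1e-6), x[3], x[4], center),
    affine = affine_transform(matrix(c(x[1], x[3], x[2], x[4]), 2, 2),
                              x[5], x[6], center))
}

# downsampled copies for the driver's own coarse-to-fine schedule
mini_pyramid <- function(img, n) {
  out <- vector("list", n)
  out[[1]] <- img
  if (n > 1)
    for (k in 2:n) {
      sm <- cpp_gauss_blur(out[[k - 1]], 2 / 3)
      out[[k]] <- sm[seq(1, nrow(sm), 2), seq(1, ncol(sm), 2), drop = FALSE]
    }
  out
}

#' Register two images with a parametric transform
#'
#' Estimates the transform mapping fixed-image coordinates into the moving
#' image by minimizing negated Mattes mutual information with adaptive
#' stochastic gradient descent over a coarse-to-fine schedule of Gaussian
#' pyramids. Gradients are central finite differences on the sampled metric
#' with a common sample set per iteration.
#'
#' By default the moving image is initialized at the geometric center of the
#' fixed image (translation aligning the two image centers); the rotation
#' center is the fixed image's geometric center.
#'
#' @param fixed,moving grayscale matrices (0..255); RGB arrays are converted
#'   to luminance.
#' @param model `"similarity"` (default), `"rigid"` or `"affine"`.
#' @param config a [reg_config()].
#' @param init optional initial `wsi_transform`.
#' @param seed RNG seed for metric sampling.
#' @return `list(transform, metric, status, per_level)` of class
#'   `wsi_reg_fit`; `status` is `"ok"` or `"diverged"` (best-so-far
#'   parameters are still returned).
#' @export
register <- function(fixed, moving, model = c("similarity", "rigid", "affine"),
                     config = reg_config(), init = NULL, seed = NULL) {
  model <- match.arg(model)
  fixed <- to_gray(fixed); moving <- to_gray(moving)
  if (length(fixed) == 0 || length(moving) == 0) stop("empty image")
  Wf <- ncol(fixed); Hf <- nrow(fixed)
  center <- c((Wf - 1) / 2, (Hf - 1) / 2)
  radius <- sqrt(sum(pmax(center, c(Wf, Hf) - 1 - center)^2))
  center_m <- c((ncol(moving) - 1) / 2, (nrow(moving) - 1) / 2)
  if (is.null(init)) {
    d <- center_m - center
    init <- similarity_transform(0, 1, d[1], d[2], center)
  }
  x0 <- params_from_transform(model, init)
  scales <- param_scales(model, radius)
  n_res <- max(1, min(config$n_resolutions,
                      floor(log2(min(Hf, Wf, nrow(moving), ncol(moving)) / 32)) + 1))
  fpyr <- mini_pyramid(fixed, n_res)
  mpyr <- mini_pyramid(moving, n_res)
  frange <- range(fixed); mrange <- range(moving)
  if (diff(frange) == 0 || diff(mrange) == 0)
    stop("constant image cannot be registered")

  with_seed(seed, {
    x <- x0
    per_level <- list()
    eval_metric <- function(x, F, M_coef, f, n, exhaustive = FALSE) {
      p <- sample_coords(c(ncol(F), nrow(F)), n, exhaustive)
      fv <- cpp_interp(F, p[, 1], p[, 2], 1L, 0)
      tr <- params_to_transform(model, x, center)
      q <- transform_point(tr, p * f) / f
      mi_eval(M_coef, fv, q, config$n_bins, frange, mrange,
              config$min_overlap)$value
    }
    for (lev in seq(n_res - 1, 0)) {
      f <- 2^lev
      F <- fpyr[[lev + 1]]
      M <- mpyr[[lev + 1]]
      M_coef <- cpp_bspline_prefilter(M)
      dims <- c(ncol(F), nrow(F))
      h <- config$fd_step
      objective <- function(z) {
        p <- sample_coords(dims, config$n_samples)
        fv <- cpp_interp(F, p[, 1], p[, 2], 1L, 0)
        val_at <- function(zz) {
          xx <- x + scales * zz
          tr <- params_to_transform(model, xx, center)
          q <- transform_point(tr, p * f) / f
          tryCatch(
            mi_eval(M_coef, fv, q, config$n_bins, frange, mrange,
                    config$min_overlap)$value,
            error = function(e) NA_real_)
        }
        v0 <- val_at(z)
        g <- numeric(length(z))
        for (i in seq_along(z)) {
          e <- numeric(length(z)); e[i] <- h
          g[i] <- (val_at(z + e) - val_at(z - e)) / (2 * h)
        }
        list(value = v0, gradient = g)
      }
      fit <- asgd_minimize(objective, numeric(length(x0)), config)
      x <- x + scales * fit$par
      mval <- tryCatch(
        eval_metric(x, F, M_coef, f, 4096, exhaustive = length(F) <= 4096),
        error = function(e) NA_real_)
      per_level[[length(per_level) + 1]] <-
        list(level = lev, metric = mval, iterations = fit$iterations,
             trace = fit$trace)
    }
    metrics <- vapply(per_level, `[[`, numeric(1), "metric")
    status <- "ok"
    if (length(metrics) >= 3) {
      worsening <- diff(metrics) > 0
      if (length(worsening) >= 3 &&
          all(tail(worsening, 3)))
        status <- "diverged"
    }
    structure(list(transform = params_to_transform(model, x, center),
                   metric = metrics[length(metrics)], status = status,
                   per_level = per_level, model = model),
              class = "wsi_reg_fit")
  })
}

#' @export
print.wsi_reg_fit <- function(x, ...) {
  cat(sprintf("<%s registration fit  metric = %.5f  status = %s>\n",
              x$model, x$metric, x$status))
  print(x$transform)
  invisible(x)
}

#' Resample an image through a transform
#'
#' `output(p) = interpolate(image, T(p))` over a fixed-frame grid, with cubic
#' B-spline interpolation by default (order 3; order 1 = bilinear, order 0 =
#' nearest). Out-of-domain pixels are filled with `background`.
#'
#' @param image grayscale matrix or RGB array (0..255).
#' @param tr a `wsi_transform` (fixed -> moving direction).
#' @param order interpolation order: 0, 1 or 3.
#' @param background fill value.
#' @param out_dims output dimensions `c(W, H)`; defaults to the input's.
#' @export
resample_image <- function(image, tr, order = 3, background = 255,
                           out_dims = NULL) {
  rgb <- length(dim(image)) == 3
  d <- dim(image)
  out_dims <- out_dims %||% c(d[2], d[1])
  q <- transform_point(tr, grid_coords(out_dims[1], out_dims[2]))
  one <- function(ch) {
    src <- if (order == 3) cpp_bspline_prefilter(ch) else ch
    matrix(cpp_interp(src, q[, 1], q[, 2], as.integer(order), background),
           out_dims[2], out_dims[1])
  }
  if (rgb) {
    chs <- lapply(1:3, function(k) one(image[, , k]))
    array(c(chs[[1]], chs[[2]], chs[[3]]), c(out_dims[2], out_dims[1], 3))
  } else one(image)
}
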