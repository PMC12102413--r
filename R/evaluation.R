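# Colocalization evaluation. Real slide pairs have no pixel-precise ground
# truth at nucleus scale, so alignment quality is scored by the structural
# similarity (SSIM) of small patches centered on the mapped coordinates;
# synthetic pairs additionally allow exact per-point error against the
# generator's ground-truth map.

gauss_kernel_1d <- function(width, sigma) {
  r <- (width - 1) / 2
  k <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  k / sum(k)
}

#' Structural similarity index of two images
#'
#' Mean local SSIM with a Gaussian window (width 11, sigma 1.5) and
#' stabilization constants `K1 = 0.01`, `K2 = 0.03` on the declared dynamic
#' range. Ranges over [-1, 1]; 1 means identical local structure.
#'
#' @param a,b equal-sized grayscale matrices (RGB arrays are converted to
#'   luminance).
#' @param window Gaussian window width (odd).
#' @param sigma Gaussian window sigma.
#' @param K1,K2 stabilization constants.
#' @param data_range dynamic range of the data (default 255).
#' @return Mean SSIM (scalar).
#' @export
ssim <- function(a, b, window = 11, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                 data_range = 255) {
  a <- to_gray(a); b <- to_gray(b)
  if (!all(dim(a) == dim(b))) stop("images must have equal dimensions")
  if (any(dim(a) < window)) stop("images smaller than the SSIM window")
  k <- gauss_kernel_1d(window, sigma)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mu_a <- cpp_sep_filter(a, k)
  mu_b <- cpp_sep_filter(b, k)
  s_aa <- cpp_sep_filter(a * a, k) - mu_a^2
  s_bb <- cpp_sep_filter(b * b, k) - mu_b^2
  s_ab <- cpp_sep_filter(a * b, k) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * s_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2)
  mean(num / den)
}

# patch centered on a continuous point, read at base level, grayscale
centered_patch <- function(pyr, p, size_px) {
  dims <- level_dims(pyr, 0)
  half <- size_px / 2
  if (p[1] < half || p[2] < half ||
      p[1] > dims[1] - half || p[2] > dims[2] - half)
    return(NULL)
  r <- wsi_rect(round(p[1]) - half, round(p[2]) - half, size_px, size_px)
  to_gray(read_region(pyr, 0, r))
}

# rescale a matrix to the given (W, H) with cubic interpolation
rescale_to <- function(img, out_dims) {
  d <- dim(img)
  if (all(c(d[2], d[1]) == out_dims)) return(img)
  sx <- (d[2] - 1) / max(out_dims[1] - 1, 1)
  sy <- (d[1] - 1) / max(out_dims[2] - 1, 1)
  g <- grid_coords(out_dims[1], out_dims[2])
  coef <- cpp_bspline_prefilter(img)
  matrix(cpp_interp(coef, g[, 1] * sx, g[, 2] * sy, 3L, 0),
         out_dims[2], out_dims[1])
}

#' SSIM colocalization evaluation across a slide set
#'
#' For every annotation and every slide pair: extract patches of a fixed
#' physical size centered on the mapped coordinates, rescale all patches to
#' the pixel dimensions of the slide with the lowest resolution (largest
#' mpp), crop the first and last rows and columns (guarding against uneven
#' dimensions after resizing), and compute grayscale SSIM. Reports the
#' per-annotation minimum SSIM over all pairs; annotations whose patch falls
#' off any slide are excluded and counted.
#'
#' @param annotations data frame `id`, `x`, `y` in the reference slide's
#'   base coordinates.
#' @param slides named list of `pyramid_image`s; the first is the reference
#'   whose frame the annotations live in.
#' @param chains named list of `transform_chain`s mapping reference
#'   coordinates into each slide (`NULL` entry = identity, for the
#'   reference itself).
#' @param patch_px patch side in pixels at the reference mpp (default 256).
#' @return An `eval_report`: `pair_ssim` (long data frame), `min_ssim` per
#'   annotation, `excluded` count, `summary`.
#' @export
ssim_colocalization_eval <- function(annotations, slides, chains,
                                     patch_px = 256) {
  stopifnot(length(slides) >= 2, length(chains) == length(slides))
  nm <- names(slides)
  ref_mpp <- slides[[1]]$mpp_x
  patch_um <- patch_px * ref_mpp
  mpps <- vapply(slides, `[[`, numeric(1), "mpp_x")
  dims_per_slide <- lapply(mpps, function(m) {
    d <- round(patch_um / m)
    c(d, d)
  })
  target_dims <- dims_per_slide[[which.max(mpps)]]
  mapped <- lapply(seq_along(slides), function(k) {
    if (is.null(chains[[k]]))
      data.frame(id = annotations$id, x = annotations$x, y = annotations$y,
                 flag = "ok")
    else apply_chain(annotations, chains[[k]], discrete = TRUE)
  })
  pair_rows <- list()
  min_rows <- list()
  excluded <- 0
  for (i in seq_len(nrow(annotations))) {
    patches <- vector("list", length(slides))
    ok <- TRUE
    for (k in seq_along(slides)) {
      p <- c(mapped[[k]]$x[i], mapped[[k]]$y[i])
      pat <- centered_patch(slides[[k]], p, dims_per_slide[[k]][1])
      if (is.null(pat)) { ok <- FALSE; break }
      pat <- rescale_to(pat, target_dims)
      # crop first/last rows and columns
      patches[[k]] <- pat[2:(nrow(pat) - 1), 2:(ncol(pat) - 1)]
    }
    if (!ok) { excluded <- excluded + 1; next }
    vals <- c()
    for (a in seq_along(slides)) for (b in seq_along(slides)) {
      if (a >= b) next
      s <- ssim(patches[[a]], patches[[b]])
      pair_rows[[length(pair_rows) + 1]] <-
        data.frame(annotation = annotations$id[i], slide_a = nm[a],
                   slide_b = nm[b], ssim = s)
      vals <- c(vals, s)
    }
    min_rows[[length(min_rows) + 1]] <-
      data.frame(annotation = annotations$id[i], min_ssim = min(vals))
  }
  pair_ssim <- do.call(rbind, pair_rows)
  min_ssim <- do.call(rbind, min_rows)
  structure(list(pair_ssim = pair_ssim, min_ssim = min_ssim,
                 excluded = excluded,
                 summary = if (!is.null(min_ssim))
                   c(mean = mean(min_ssim$min_ssim),
                     median = median(min_ssim$min_ssim),
                     min = min(min_ssim$min_ssim)) else NULL),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<SSIM evaluation  %d annotation(s), %d excluded>\n",
              if (is.null(x$min_ssim)) 0 else nrow(x$min_ssim), x$excluded))
  if (!is.null(x$summary))
    cat(sprintf("  min-SSIM: mean %.3f  median %.3f  min %.3f\n",
                x$summary["mean"], x$summary["median"], x$summary["min"]))
  invisible(x)
}

#' Write an evaluation report as JSON plus a CSV table
#' @param report an `eval_report`.
#' @param prefix output path prefix (writes `<prefix>.json`,
#'   `<prefix>.csv`).
#' @export
write_eval_report <- function(report, prefix) {
  jsonlite::write_json(list(summary = as.list(report$summary),
                            excluded = report$excluded,
                            min_ssim = report$min_ssim),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$pair_ssim))
    write.csv(report$pair_ssim, paste0(prefix, ".csv"), row.names = FALSE)
  invisible(prefix)
}

#' Per-point colocalization error against ground truth
#'
#' Euclidean error of each predicted point against its matched ground-truth
#' point, in pixels and micrometers.
#'
#' @param predicted,truth data frames with `id`, `x`, `y`; ids must match.
#' @param mpp micrometers per pixel used for the conversion.
#' @return A `coloc_error`: per-point errors plus mean / median / p95 / max
#'   summaries.
#' @export
colocalization_error <- function(predicted, truth, mpp = 0.25) {
  if (nrow(predicted) != nrow(truth)) stop("point sets differ in size")
  m <- match(as.character(predicted$id), as.character(truth$id))
  if (anyNA(m)) stop("annotation ids do not match")
  truth <- truth[m, ]
  err_px <- sqrt((predicted$x - truth$x)^2 + (predicted$y - truth$y)^2)
  err_um <- err_px * mpp
  structure(list(per_point = data.frame(id = predicted$id, error_px = err_px,
                                        error_um = err_um),
                 mpp = mpp,
                 summary_px = c(mean = mean(err_px), median = median(err_px),
                                p95 = unname(quantile(err_px, 0.95)),
                                max = max(err_px)),
                 summary_um = c(mean = mean(err_um), median = median(err_um),
                                p95 = unname(quantile(err_um, 0.95)),
                                max = max(err_um))),
            class = "coloc_error")
}

#' @export
print.coloc_error <- function(x, ...) {
  cat(sprintf("<colocalization error  n = %d  mean %.3f um  median %.3f um  max %.3f um>\n",
              nrow(x$per_point), x$summary_um["mean"], x$summary_um["median"],
              x$summary_um["max"]))
  invisible(x)
}
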