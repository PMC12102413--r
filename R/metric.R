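# Mattes mutual-information similarity metric. Intensities are binned with a
# zero-order (box) Parzen kernel on the fixed image and a cubic B-spline
# kernel on the moving image; densities come from random coordinate samples
# in the fixed domain (or from every pixel center with exhaustive sampling).
# MI is reported in nats and negated so that registration is a minimization.

#' Registration configuration
#'
#' Defaults follow common practice for similarity-metric registration of
#' overview images: 32 histogram bins, 2048 random samples per iteration,
#' 3 resolution levels, 500 optimizer iterations per level. Refinement stages
#' override these with reduced budgets. Any field can also be overridden from
#' a flat `key = value` parameter file via [read_param_file()].
#'
#' @param n_resolutions multi-resolution levels of the registration driver.
#' @param iterations optimizer iterations per level.
#' @param n_bins histogram bins (>= 8).
#' @param n_samples random coordinate samples per metric evaluation.
#' @param sampling `"random"` or `"exhaustive"` (all pixel centers).
#' @param min_overlap minimal fraction of samples that must land inside the
#'   moving image.
#' @param asgd_a,asgd_A,asgd_alpha adaptive stochastic gradient descent
#'   constants; `asgd_a = NULL` auto-scales from `step_target`.
#' @param step_target target initial step, in pixels of induced point motion.
#' @param max_step trust-region cap on a single step (pixels of induced
#'   motion); guards the auto-scaled schedule against noisy first gradients.
#' @param tol step-norm convergence tolerance (scaled parameter units).
#' @param fd_step central finite-difference step (scaled parameter units).
#' @export
reg_config <- function(n_resolutions = 3, iterations = 500, n_bins = 32,
                       n_samples = 2048, sampling = c("random", "exhaustive"),
                       min_overlap = 0.25, asgd_a = NULL, asgd_A = 20,
                       asgd_alpha = 1, step_target = 1, max_step = 5,
                       tol = 1e-4, fd_step = 0.5) {
  sampling <- match.arg(sampling)
  stopifnot(n_resolutions >= 1, iterations >= 1, n_bins >= 8, n_samples >= 1)
  structure(list(n_resolutions = n_resolutions, iterations = iterations,
                 n_bins = n_bins, n_samples = n_samples, sampling = sampling,
                 min_overlap = min_overlap, asgd_a = asgd_a, asgd_A = asgd_A,
                 asgd_alpha = asgd_alpha, step_target = step_target,
                 max_step = max_step, tol = tol, fd_step = fd_step),
            class = "reg_config")
}

#' Override a configuration from a flat parameter file
#'
#' The file holds one `key = value` pair per line (`#` comments allowed);
#' keys must be fields of [reg_config()]. Values are parsed as numerics where
#' possible.
#'
#' @param path parameter file path.
#' @param config configuration to override.
#' @export
read_param_file <- function(path, config = reg_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed parameter line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(config)) stop("unknown parameter: ", key)
    num <- suppressWarnings(as.numeric(val))
    config[[key]] <- if (!is.na(num)) num else val
  }
  config
}

# sample fixed-domain coordinates (0-based, continuous) for one metric
# evaluation; exhaustive sampling uses every pixel center
sample_coords <- function(dims, n, exhaustive = FALSE) {
  W <- dims[1]; H <- dims[2]
  if (exhaustive) {
    g <- expand.grid(x = 0:(W - 1), y = 0:(H - 1))
    return(cbind(g$x, g$y))
  }
  cbind(runif(n, 0, W - 1), runif(n, 0, H - 1))
}

# internal fast path: precomputed moving-image B-spline coefficients and
# intensity ranges, sample points already drawn
mi_eval <- function(movcoef, fvals, q, n_bins, frange, mrange, min_overlap) {
  res <- cpp_mattes_mi(movcoef, fvals, q[, 1], q[, 2], as.integer(n_bins),
                       frange[1], frange[2], mrange[1], mrange[2])
  if (res$fraction < min_overlap)
    stop(sprintf("insufficient overlap: %.1f%% of samples inside the moving image",
                 100 * res$fraction))
  res
}

#' Negated Mattes mutual information between two images under a transform
#'
#' Draws coordinate samples in the fixed domain, maps them through `tr`
#' (fixed -> moving) and estimates the joint intensity density with Parzen
#' windows (box kernel over fixed intensities, cubic B-spline kernel over
#' moving intensities). Returns minus the mutual information in nats, so
#' smaller is better.
#'
#' @param fixed,moving grayscale matrices (0..255).
#' @param tr a `wsi_transform` mapping fixed into moving coordinates.
#' @param config a [reg_config()].
#' @param seed RNG seed for the coordinate sampler.
#' @return Negated MI (numeric scalar) with attributes `n_inside` and
#'   `fraction`.
#' @export
mattes_mi <- function(fixed, moving, tr = identity_transform(),
                      config = reg_config(), seed = NULL) {
  fixed <- to_gray(fixed); moving <- to_gray(moving)
  frange <- range(fixed); mrange <- range(moving)
  if (diff(frange) == 0 || diff(mrange) == 0) {
    warning("constant image: mutual information is zero")
    return(structure(0, n_inside = length(fixed), fraction = 1))
  }
  p <- with_seed(seed, sample_coords(c(ncol(fixed), nrow(fixed)),
                                     config$n_samples,
                                     config$sampling == "exhaustive"))
  fvals <- cpp_interp(fixed, p[, 1], p[, 2], 1L, 0)
  q <- transform_point(tr, p)
  movcoef <- cpp_bspline_prefilter(moving)
  res <- mi_eval(movcoef, fvals, q, config$n_bins, frange, mrange,
                 config$min_overlap)
  structure(res$value, n_inside = res$n_inside, fraction = res$fraction)
}
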