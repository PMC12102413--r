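# End-to-end orchestration: preprocess (orientation, segmentation, ROIs) ->
# coarse registration -> extrapolation -> refinement -> transform chain.
# register_slides() is the package's fitting function; the returned object
# behaves like a fitted model whose predict() maps point sets into the
# moving slide.

#' Register two whole-slide images for point colocalization
#'
#' Runs the full hierarchical pipeline: orientation harmonization of the
#' moving slide, tissue segmentation (unless ROIs are supplied), coarse
#' similarity registration of the overview levels, extrapolation to the
#' base layer, and the selected base-layer refinement — grid tiles
#' (Strategy I, suited to spatially clustered annotations) or
#' per-annotation patches (Strategy II, suited to sparse annotations).
#' The result is a fitted registration whose [predict()][predict.slide_registration]
#' method maps points from the fixed slide's base coordinates into the
#' moving slide's.
#'
#' @param fixed,moving `pyramid_image`s; the fixed slide is the reference
#'   whose coordinates the annotations live in.
#' @param annotations optional data frame `id`, `x`, `y` (base-layer pixels
#'   of the fixed slide). Without annotations only the coarse stage runs.
#' @param strategy `"auto"` (cost-based recommendation), `"1"`, `"2"`, or
#'   `"coarse"` (no refinement).
#' @param orientation dihedral op applied to the moving slide before
#'   registration (configured, not detected); the returned chain maps into
#'   the moving slide's original frame.
#' @param roi_fixed,roi_moving optional manual ROI overrides
#'   ([wsi_rect()], base coordinates; the moving ROI refers to the oriented
#'   frame when `orientation != "none"`).
#' @param tile_size Strategy-I tile side in base px.
#' @param patch_size Strategy-II patch side in base px (64..1024).
#' @param coarse_config,refine_config [reg_config()]s for the two stages.
#' @param seed global seed; all stochastic sampling derives from it.
#' @param smooth smooth Strategy-I corrections across tiles when predicting.
#' @return An object of class `slide_registration`.
#' @export
register_slides <- function(fixed, moving, annotations = NULL,
                            strategy = c("auto", "1", "2", "coarse"),
                            orientation = "none",
                            roi_fixed = NULL, roi_moving = NULL,
                            tile_size = 2048, patch_size = 192,
                            coarse_config = reg_config(),
                            refine_config = reg_config(n_resolutions = 2,
                                                       iterations = 250),
                            seed = 1, smooth = FALSE) {
  strategy <- match.arg(strategy)
  orientation <- match.arg(orientation, orientation_ops())
  cl <- match.call()
  seeds <- with_seed(seed, sample.int(2^30, 4))
  moving_work <- orient_pyramid(moving, orientation)
  if (is.null(roi_fixed)) roi_fixed <- auto_roi(fixed)
  if (is.null(roi_moving)) roi_moving <- auto_roi(moving_work)
  cr <- coarse_register(fixed, moving_work, roi_fixed, roi_moving,
                        config = coarse_config, seed = seeds[1])
  base_tr <- extrapolate_to_base(cr)
  if (strategy == "auto") {
    strategy <- if (is.null(annotations)) "coarse"
      else choose_strategy(annotations, roi_fixed, tile_size,
                           patch_size)$recommendation
    strategy <- sub("strategy", "", strategy)
  }
  # reference resolution: base layer of the lower-resolution slide; the
  # matching level of the other pyramid is used for refinement reads
  mpp_f <- fixed$mpp_x; mpp_m <- moving_work$mpp_x
  ref_mpp <- max(mpp_f, mpp_m)
  level_f <- min(max(0L, round(log2(ref_mpp / mpp_f))), n_levels(fixed) - 1L)
  level_m <- min(max(0L, round(log2(ref_mpp / mpp_m))),
                 n_levels(moving_work) - 1L)
  steps <- list(chain_step_global(base_tr, created = 1))
  refinement <- NULL
  if (strategy == "1" && !is.null(annotations)) {
    grid <- build_grid(roi_fixed, tile_size = tile_size,
                       annotations = annotations)
    tiles <- refine_tiles_strategy1(grid, base_tr, fixed, moving_work,
                                    config = refine_config,
                                    level_f = level_f, level_m = level_m,
                                    seed = seeds[2])
    inv_base <- invert_transform(base_tr)
    step_tiles <- lapply(seq_along(tiles), function(k) {
      tl <- tiles[[k]]
      gtl <- grid$tiles[[tl$index]]
      corr <- compose_transforms(
        compose_transforms(base_tr, tl$transform), inv_base)
      list(rect = tl$rect, correction = corr, status = tl$status,
           row = gtl$row, col = gtl$col)
    })
    steps[[2]] <- chain_step_tiles(step_tiles, grid$roi, grid$tile_w,
                                   grid$tile_h, c(grid$nx, grid$ny),
                                   created = 2)
    refinement <- list(kind = "tiles", grid = grid, tiles = tiles)
  } else if (strategy == "2" && !is.null(annotations)) {
    pseeds <- with_seed(seeds[3],
                        sample.int(.Machine$integer.max, nrow(annotations)))
    inv_base <- invert_transform(base_tr)
    corrections <- lapply(seq_len(nrow(annotations)), function(i) {
      pc <- refine_point_strategy2(c(annotations$x[i], annotations$y[i]),
                                   base_tr, fixed, moving_work,
                                   patch_size = patch_size,
                                   config = refine_config,
                                   level_f = level_f, level_m = level_m,
                                   seed = pseeds[i], id = annotations$id[i])
      corr <- if (!is.null(pc$transform) && pc$status == "ok")
        compose_transforms(compose_transforms(base_tr, pc$transform),
                           inv_base)
      else NULL
      list(id = pc$id, status = pc$status, correction = corr,
           metric = pc$metric)
    })
    steps[[2]] <- chain_step_points(corrections, created = 2)
    refinement <- list(kind = "points", corrections = corrections)
  }
  if (orientation != "none") {
    od <- level_dims(moving_work, 0)
    steps[[length(steps) + 1]] <-
      chain_step_orientation(orientation_inverse(orientation), od,
                             created = length(steps) + 1)
  }
  chain <- compose_chain(steps, strategy = strategy,
                         metadata = list(
                           levels = c(cr$level_f, cr$level_m),
                           refine_levels = c(level_f, level_m),
                           roi_fixed = rect_to_list(roi_fixed),
                           roi_moving = rect_to_list(roi_moving),
                           orientation = orientation,
                           tile_size = tile_size, patch_size = patch_size,
                           seed = seed))
  mapped <- if (!is.null(annotations))
    apply_chain(annotations, chain, smooth = smooth) else NULL
  structure(list(chain = chain, coarse = cr, base_transform = base_tr,
                 refinement = refinement, strategy = strategy,
                 roi_fixed = roi_fixed, roi_moving = roi_moving,
                 orientation = orientation, annotations = annotations,
                 mapped = mapped, seed = seed, smooth = smooth, call = cl),
            class = "slide_registration")
}

#' @export
print.slide_registration <- function(x, ...) {
  cat("Whole-slide registration for point colocalization\n")
  cat(sprintf("  strategy: %s   coarse levels: (%d, %d)   seed: %s\n",
              x$strategy, x$coarse$level_f, x$coarse$level_m, x$seed))
  cat("  base transform: ")
  print(x$base_transform)
  if (!is.null(x$refinement)) {
    if (x$refinement$kind == "tiles") {
      st <- vapply(x$refinement$tiles, `[[`, character(1), "status")
      cat(sprintf("  refinement: %d tile(s) (%d ok, %d failed), %s registered\n",
                  length(st), sum(st == "ok"), sum(st != "ok"),
                  format_megapixels(count_registered_pixels(
                    length(st), x$chain$metadata$tile_size))))
    } else {
      st <- vapply(x$refinement$corrections, `[[`, character(1), "status")
      cat(sprintf("  refinement: %d point correction(s) (%d ok)\n",
                  length(st), sum(st == "ok")))
    }
  }
  invisible(x)
}

#' @export
summary.slide_registration <- function(object, ...) {
  print(object)
  cat(sprintf("  coarse metric: %.5f (%s)\n", object$coarse$metric,
              object$coarse$status))
  if (!is.null(object$mapped)) {
    cat(sprintf("  mapped annotations: %d (%d flagged)\n",
                nrow(object$mapped), sum(object$mapped$flag != "ok")))
  }
  invisible(object)
}

#' Extract the base-layer transform parameters
#' @param object a `slide_registration`.
#' @param ... unused.
#' @export
coef.slide_registration <- function(object, ...) {
  tr <- object$base_transform
  c(angle = tr$angle, scale = tr$scale, tx = tr$tx, ty = tr$ty,
    cx = tr$center[1], cy = tr$center[2])
}

#' Map points into the moving slide
#'
#' Without `newdata`, returns the mapped coordinates of the annotations the
#' registration was fitted with. With `newdata`, re-applies the stored
#' chain: arbitrary new points for coarse-only and Strategy-I fits;
#' Strategy-II fits refuse unseen annotation ids (their corrections are
#' per-annotation).
#'
#' @param object a `slide_registration`.
#' @param newdata optional data frame `id`, `x`, `y`.
#' @param discrete round outputs to integer pixels (default).
#' @param ... unused.
#' @export
predict.slide_registration <- function(object, newdata = NULL,
                                       discrete = TRUE, ...) {
  if (is.null(newdata)) {
    if (is.null(object$mapped)) stop("no annotations were supplied; pass newdata")
    return(object$mapped)
  }
  reuse_chain(newdata, object$chain, discrete = discrete,
              smooth = object$smooth)
}

#' Overlay plot of the coarse alignment
#'
#' Fixed ROI overview in red, coarse-warped moving ROI overview in green;
#' aligned tissue appears dark yellow.
#'
#' @param x a `slide_registration`.
#' @param fixed,moving the registered `pyramid_image`s.
#' @param ... passed to [graphics::rasterImage()].
#' @export
plot.slide_registration <- function(x, fixed, moving, ...) {
  cr <- x$coarse
  moving_work <- orient_pyramid(moving, x$orientation)
  crop_f <- to_gray(read_region(fixed, cr$level_f, cr$roi_f))
  crop_m <- to_gray(read_region(moving_work, cr$level_m, cr$roi_m))
  warped <- resample_image(crop_m, cr$transform, order = 1,
                           out_dims = c(ncol(crop_f), nrow(crop_f)))
  arr <- array(0, c(dim(crop_f), 3))
  arr[, , 1] <- 1 - crop_f / 255
  arr[, , 2] <- 1 - warped / 255
  op <- par(mar = c(1, 1, 2, 1))
  on.exit(par(op))
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
       main = "coarse alignment (fixed = red, moving = green)")
  graphics::rasterImage(arr, 0, 0, 1, 1, ...)
  invisible(x)
}

# ---- run configuration and manifest ----------------------------------------

# 31-ary polynomial rolling hash (mod 2^31): a stable fingerprint of the
# serialized configuration for the run manifest
config_hash <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline from a stored configuration
#'
#' Reads slides and annotations from disk, fits the registration, and
#' writes the chain JSON, the mapped coordinates, a JSON-lines audit of
#' per-tile / per-point results and a run manifest (config echo, hash,
#' seed). Re-running with the stored configuration reproduces the outputs
#' bit-identically.
#'
#' @param config named list (or path to a JSON file) with fields `fixed`,
#'   `moving` (pyramidal TIFF paths), `annotations` (CSV/JSON path,
#'   optional), `out_dir`, and optionally `strategy`, `orientation`,
#'   `tile_size`, `patch_size`, `roi_fixed` / `roi_moving` (`list(x, y, w,
#'   h)`), `param_file`, `seed`.
#' @return The run manifest (invisibly), after writing all outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(!is.null(config$fixed), !is.null(config$moving),
            !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fixed <- read_pyramid_tiff(config$fixed)
  moving <- read_pyramid_tiff(config$moving)
  ann <- if (!is.null(config$annotations)) read_points(config$annotations)
         else NULL
  if (!is.null(ann) && is.null(ann$id)) ann$id <- seq_len(nrow(ann))
  cc <- reg_config(); rc <- reg_config(n_resolutions = 2, iterations = 250)
  if (!is.null(config$param_file)) {
    cc <- read_param_file(config$param_file, cc)
  }
  as_rect <- function(l) if (is.null(l)) NULL else wsi_rect(l$x, l$y, l$w, l$h)
  fit <- register_slides(
    fixed, moving, annotations = ann,
    strategy = config$strategy %||% "auto",
    orientation = config$orientation %||% "none",
    roi_fixed = as_rect(config$roi_fixed),
    roi_moving = as_rect(config$roi_moving),
    tile_size = config$tile_size %||% 2048,
    patch_size = config$patch_size %||% 192,
    coarse_config = cc, refine_config = rc,
    seed = config$seed %||% 1)
  chain_path <- file.path(config$out_dir, "chain.json")
  write_chain(fit$chain, chain_path)
  if (!is.null(fit$mapped))
    write_points(fit$mapped, file.path(config$out_dir, "mapped_points.csv"))
  audit_path <- file.path(config$out_dir, "audit.jsonl")
  audit <- file(audit_path, "w")
  if (!is.null(fit$refinement)) {
    if (fit$refinement$kind == "tiles") {
      for (tl in fit$refinement$tiles)
        writeLines(jsonlite::toJSON(list(kind = "tile", index = tl$index,
                                         status = tl$status,
                                         metric = tl$metric),
                                    auto_unbox = TRUE, digits = NA), audit)
    } else {
      for (cc2 in fit$refinement$corrections)
        writeLines(jsonlite::toJSON(list(kind = "point", id = cc2$id,
                                         status = cc2$status,
                                         metric = cc2$metric),
                                    auto_unbox = TRUE, digits = NA), audit)
    }
  }
  close(audit)
  manifest <- list(package = "wsicoloc",
                   version = as.character(utils::packageVersion("wsicoloc")),
                   seed = config$seed %||% 1,
                   strategy = fit$strategy,
                   config = config,
                   config_hash = config_hash(
                     as.character(jsonlite::toJSON(config, auto_unbox = TRUE))),
                   outputs = list(chain = chain_path, audit = audit_path))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
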