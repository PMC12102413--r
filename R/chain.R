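# Ordered transformation chains. Registration produces parameters; applying
# them to concrete coordinates is decoupled, so a stored chain can map any
# later point set (Strategy I) or exactly the annotation set it was built
# for (Strategy II). Steps are applied strictly in the order in which they
# were created. Tile and point corrections are stored as moving-domain
# transforms (the base-transform conjugate of the locally estimated
# correction), so successive application of the steps reproduces
# base-then-refinement composition exactly; their applicability domains
# (tile rects, annotation ids) are resolved against the original fixed
# coordinates.

chain_step_orientation <- function(op, dims, created = NA) {
  list(kind = "orientation", op = op, dims = as.numeric(dims),
       created = created)
}

chain_step_global <- function(transform, created = NA) {
  list(kind = "global", transform = transform, created = created)
}

# tiles: list of list(rect, correction, status, row, col); grid_dims = c(nx, ny)
chain_step_tiles <- function(tiles, roi, tile_w, tile_h, grid_dims,
                             created = NA) {
  list(kind = "tiles", tiles = tiles, roi = roi, tile_w = tile_w,
       tile_h = tile_h, grid_dims = grid_dims, created = created)
}

chain_step_points <- function(corrections, created = NA) {
  list(kind = "points", corrections = corrections, created = created)
}

#' Compose an ordered transformation chain
#'
#' Validates that steps are supplied in creation order, that tile domains do
#' not overlap and that per-point corrections carry unique annotation ids.
#' An empty step list yields the identity chain.
#'
#' @param steps list of chain steps (built internally by the pipeline; see
#'   [register_slides()]).
#' @param strategy `"coarse"`, `"1"` or `"2"` — which refinement built the
#'   chain.
#' @param metadata provenance list (levels, ROIs, seeds) stored verbatim.
#' @return A `transform_chain`.
#' @export
compose_chain <- function(steps = list(), strategy = "coarse",
                          metadata = list()) {
  created <- vapply(steps, function(s) as.numeric(s$created %||% NA), numeric(1))
  if (any(!is.na(created)) && is.unsorted(created[!is.na(created)], strictly = TRUE))
    stop("steps must be supplied in creation order")
  for (s in steps) {
    if (s$kind == "tiles" && length(s$tiles) > 1) {
      rects <- lapply(s$tiles, `[[`, "rect")
      for (i in seq_along(rects)) for (j in seq_len(i - 1))
        if (!is.null(rect_intersect(rects[[i]], rects[[j]])))
          stop("tile domains overlap: two tiles would claim the same point")
    }
    if (s$kind == "points") {
      ids <- vapply(s$corrections, function(cc) as.character(cc$id), character(1))
      if (anyDuplicated(ids)) stop("duplicate annotation ids in point corrections")
    }
  }
  structure(list(steps = steps, strategy = strategy, metadata = metadata,
                 version = 1L),
            class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  kinds <- vapply(x$steps, `[[`, character(1), "kind")
  cat(sprintf("<transform chain  strategy %s  steps: %s>\n", x$strategy,
              if (length(kinds)) paste(kinds, collapse = " -> ") else "identity"))
  invisible(x)
}

#' Map points through a transformation chain
#'
#' Applies every step in creation order to the continuous coordinates, then
#' discretizes with round-half-to-even. Points outside every tile domain (or
#' without a per-point correction) are flagged and keep their base-transform
#' mapping. With `smooth = TRUE` and a complete tile grid, the per-tile
#' displacement samples (taken at tile centers) are interpolated with a
#' separable cubic B-spline across tiles instead of applying each tile's
#' transform piecewise; per-point corrections are exact and never smoothed.
#'
#' @param points data frame with columns `x`, `y` and optionally `id`.
#' @param chain a `transform_chain`.
#' @param discrete round the final coordinates to integers (default).
#' @param smooth smooth Strategy-I corrections across tile boundaries
#'   (default off: tiles are treated independently).
#' @return Data frame `id`, `x`, `y`, `flag` (`"ok"`, `"outside_tiles"` or
#'   `"uncorrected"`).
#' @export
apply_chain <- function(points, chain, discrete = TRUE, smooth = FALSE) {
  stopifnot(inherits(chain, "transform_chain"))
  pts <- as.data.frame(points)
  if (is.null(pts$id)) pts$id <- seq_len(nrow(pts))
  orig <- as.matrix(pts[, c("x", "y")])
  cur <- orig
  flag <- rep("ok", nrow(pts))
  prior <- list()
  apply_prior <- function(p) {
    for (s in prior) {
      p <- switch(s$kind,
        orientation = apply_orientation_pretransform(p, s$op, s$dims),
        global = transform_point(s$transform, p),
        p)
    }
    p
  }
  for (s in chain$steps) {
    if (s$kind == "orientation") {
      cur <- apply_orientation_pretransform(cur, s$op, s$dims)
    } else if (s$kind == "global") {
      cur <- transform_point(s$transform, cur)
    } else if (s$kind == "tiles") {
      nx <- s$grid_dims[1]; ny <- s$grid_dims[2]
      full <- length(s$tiles) == nx * ny
      if (smooth && full && nx >= 2 && ny >= 2) {
        centers <- t(vapply(s$tiles, function(tl) rect_center(tl$rect),
                            numeric(2)))
        qc <- apply_prior(centers)
        dd <- t(vapply(seq_along(s$tiles), function(k) {
          transform_point(s$tiles[[k]]$correction, qc[k, ]) - qc[k, ]
        }, numeric(2)))
        rows <- vapply(s$tiles, `[[`, numeric(1), "row")
        cols <- vapply(s$tiles, `[[`, numeric(1), "col")
        dxg <- matrix(NA_real_, ny, nx); dyg <- dxg
        dxg[cbind(rows + 1, cols + 1)] <- dd[, 1]
        dyg[cbind(rows + 1, cols + 1)] <- dd[, 2]
        gx <- (orig[, 1] - s$roi$x) / s$tile_w - 0.5
        gy <- (orig[, 2] - s$roi$y) / s$tile_h - 0.5
        inside <- gx > -0.5 & gx < nx - 0.5 & gy > -0.5 & gy < ny - 0.5
        gx <- pmin(pmax(gx, 0), nx - 1); gy <- pmin(pmax(gy, 0), ny - 1)
        ddx <- cpp_interp(cpp_bspline_prefilter(dxg), gx, gy, 3L, 0)
        ddy <- cpp_interp(cpp_bspline_prefilter(dyg), gx, gy, 3L, 0)
        cur[inside, 1] <- cur[inside, 1] + ddx[inside]
        cur[inside, 2] <- cur[inside, 2] + ddy[inside]
        flag[!inside] <- "outside_tiles"
      } else {
        if (smooth && !full)
          warning("incomplete tile grid; applying tiles independently")
        claimed <- rep(FALSE, nrow(pts))
        for (tl in s$tiles) {
          r <- tl$rect
          inr <- orig[, 1] >= r$x & orig[, 1] < r$x + r$w &
                 orig[, 2] >= r$y & orig[, 2] < r$y + r$h & !claimed
          if (any(inr)) {
            cur[inr, ] <- transform_point(tl$correction,
                                          cur[inr, , drop = FALSE])
            claimed <- claimed | inr
          }
        }
        flag[!claimed] <- "outside_tiles"
      }
    } else if (s$kind == "points") {
      ids <- vapply(s$corrections, function(cc) as.character(cc$id),
                    character(1))
      pos <- match(as.character(pts$id), ids)
      for (i in seq_len(nrow(pts))) {
        if (is.na(pos[i])) {
          flag[i] <- "uncorrected"
        } else {
          cc <- s$corrections[[pos[i]]]
          if (is.null(cc$correction) || !identical(cc$status, "ok")) {
            flag[i] <- "uncorrected"
          } else {
            cur[i, ] <- transform_point(cc$correction, cur[i, ])
          }
        }
      }
    }
    prior[[length(prior) + 1]] <- s
  }
  if (discrete) cur <- round(cur)
  data.frame(id = pts$id, x = cur[, 1], y = cur[, 2], flag = flag)
}

#' Re-apply a stored chain to a new point set
#'
#' Strategy-I (and coarse-only) chains map arbitrary new points without
#' re-registration and bit-identically across processes. Strategy-II chains
#' carry per-annotation corrections only, so presenting unseen annotation
#' ids is an error.
#'
#' @inheritParams apply_chain
#' @export
reuse_chain <- function(points, chain, discrete = TRUE, smooth = FALSE) {
  stopifnot(inherits(chain, "transform_chain"))
  if (identical(chain$strategy, "2")) {
    stored <- unlist(lapply(chain$steps, function(s)
      if (s$kind == "points")
        vapply(s$corrections, function(cc) as.character(cc$id), character(1))))
    ids <- if (is.null(points$id)) as.character(seq_len(nrow(points)))
           else as.character(points$id)
    if (!all(ids %in% stored))
      stop("Strategy-II chains are not reusable for unseen annotations; ",
           "re-run the per-annotation correction for new points")
  }
  apply_chain(points, chain, discrete = discrete, smooth = smooth)
}

# ---- serialization ----------------------------------------------------------

rect_to_list <- function(r) list(x = r$x, y = r$y, w = r$w, h = r$h)
rect_from_list <- function(l) wsi_rect(l$x, l$y, l$w, l$h)

step_to_list <- function(s) {
  out <- switch(s$kind,
    orientation = list(kind = "orientation", op = s$op, dims = s$dims),
    global = list(kind = "global", transform = transform_to_list(s$transform)),
    tiles = list(kind = "tiles",
                 roi = rect_to_list(s$roi), tile_w = s$tile_w,
                 tile_h = s$tile_h, grid_dims = s$grid_dims,
                 tiles = lapply(s$tiles, function(tl)
                   list(rect = rect_to_list(tl$rect),
                        correction = transform_to_list(tl$correction),
                        status = tl$status, row = tl$row, col = tl$col))),
    points = list(kind = "points",
                  corrections = lapply(s$corrections, function(cc)
                    list(id = cc$id, status = cc$status,
                         correction = if (is.null(cc$correction)) NULL
                                      else transform_to_list(cc$correction)))))
  out$created <- s$created
  out
}

step_from_list <- function(l) {
  switch(l$kind,
    orientation = chain_step_orientation(l$op, unlist(l$dims), l$created),
    global = chain_step_global(transform_from_list(l$transform), l$created),
    tiles = chain_step_tiles(
      lapply(l$tiles, function(tl)
        list(rect = rect_from_list(tl$rect),
             correction = transform_from_list(tl$correction),
             status = tl$status, row = tl$row, col = tl$col)),
      rect_from_list(l$roi), l$tile_w, l$tile_h, unlist(l$grid_dims),
      l$created),
    points = chain_step_points(
      lapply(l$corrections, function(cc)
        list(id = cc$id, status = cc$status,
             correction = if (is.null(cc$correction)) NULL
                          else transform_from_list(cc$correction))),
      l$created),
    stop("unknown chain step kind: ", l$kind))
}

#' Serialize / load a transformation chain as versioned JSON
#'
#' The JSON carries an explicit convention block (0-based pixel frame,
#' degrees, CCW-positive in y-down, fixed-to-moving direction) and full
#' double precision, so a reloaded chain reproduces coordinates
#' bit-identically.
#'
#' @param chain a `transform_chain`.
#' @param path output / input JSON path.
#' @export
write_chain <- function(chain, path) {
  obj <- list(format = "wsicoloc-chain", version = chain$version,
              convention = list(frame = "0-based pixels, x right, y down",
                                angle = "degrees, CCW-positive in y-down",
                                direction = "fixed -> moving"),
              strategy = chain$strategy, metadata = chain$metadata,
              steps = lapply(chain$steps, step_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "wsicoloc-chain"))
    stop("not a transform chain file")
  compose_chain(lapply(obj$steps, step_from_list), strategy = obj$strategy,
                metadata = obj$metadata)
}
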