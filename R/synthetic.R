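# Synthetic re-stained / re-scanned slide pairs. The generator emulates the
# variation sources seen between a scanned H&E slide and its re-stained,
# re-scanned counterpart: a global similarity misalignment, right-angle
# orientation changes, a different scan resolution (mpp), differing scan
# extents, low-amplitude smooth tissue deformation from the re-staining
# chemistry, stain appearance change (H&E-like vs IHC-like with DAB rings on
# a nucleus subset), and intensity noise. Every pair carries a closed-form
# ground-truth point mapping, which real slide pairs never have — it is the
# evaluation oracle for the registration pipeline.

#' Describe a synthetic re-scan scenario
#'
#' Defaults give the identity scenario (moving = fixed). The composed
#' forward mapping from fixed to moving base coordinates is, in order:
#' extent offset, orientation op, global similarity (about the oriented
#' frame's center, with scale `scale / mpp_ratio`), then a smooth local
#' displacement applied in the moving domain.
#'
#' @param angle,scale,tx,ty global similarity misalignment (degrees, factor
#'   in `[0.8, 1.25]`, pixels).
#' @param orientation_op one of the eight dihedral ops.
#' @param stain_model `"he"` (appearance kept) or `"ihc"` (hematoxylin-like
#'   nuclei plus DAB-brown rings on a random nucleus subset).
#' @param mpp_ratio moving mpp / fixed mpp (approx. 1 +- 0.1 between real
#'   scanners).
#' @param deform_amplitude maximum displacement (px) of the smooth local
#'   deformation field; 0 disables it.
#' @param deform_smoothness correlation length (px) of the deformation.
#' @param extent_offset `c(dx, dy)`: shift of the moving scan's origin
#'   relative to the fixed scan (differing scanned extents).
#' @param noise_sigma additive Gaussian intensity noise (0..255 scale).
#' @param dab_fraction fraction of nuclei receiving a DAB ring under the
#'   IHC model.
#' @param seed scenario RNG seed (drives deformation, stain and noise).
#' @export
slide_scenario <- function(angle = 0, scale = 1, tx = 0, ty = 0,
                           orientation_op = "none",
                           stain_model = c("he", "ihc"), mpp_ratio = 1,
                           deform_amplitude = 0, deform_smoothness = 200,
                           extent_offset = c(0, 0), noise_sigma = 0,
                           dab_fraction = 0.3, seed = 1) {
  stain_model <- match.arg(stain_model)
  orientation_op <- match.arg(orientation_op, orientation_ops())
  if (scale < 0.8 || scale > 1.25)
    stop("scale must lie in [0.8, 1.25]")
  if (deform_amplitude < 0) stop("deformation amplitude must be >= 0")
  structure(list(angle = angle, scale = scale, tx = tx, ty = ty,
                 orientation_op = orientation_op, stain_model = stain_model,
                 mpp_ratio = mpp_ratio, deform_amplitude = deform_amplitude,
                 deform_smoothness = deform_smoothness,
                 extent_offset = extent_offset, noise_sigma = noise_sigma,
                 dab_fraction = dab_fraction, seed = as.integer(seed)),
            class = "slide_scenario")
}

#' A randomized scenario within the study's stated variation ranges
#'
#' Draws a similarity misalignment with |angle| <= 15 degrees, scale in
#' [0.95, 1.1] and translation components within +-70 px, optionally adding
#' the smooth re-staining deformation.
#'
#' @param seed RNG seed.
#' @param deform_amplitude deformation amplitude in px (default 0).
#' @param stain_model `"he"` or `"ihc"`.
#' @param noise_sigma additive noise level.
#' @export
random_scenario <- function(seed, deform_amplitude = 0, stain_model = "he",
                            noise_sigma = 0) {
  with_seed(seed, {
    slide_scenario(angle = runif(1, -15, 15),
                   scale = runif(1, 0.95, 1.1),
                   tx = runif(1, -70, 70), ty = runif(1, -70, 70),
                   stain_model = stain_model,
                   deform_amplitude = deform_amplitude,
                   noise_sigma = noise_sigma,
                   seed = sample.int(1e6, 1))
  })
}

# smooth unit-scale random field of the given dims (W, H), generated at a
# coarse grid and upsampled
smooth_field <- function(dims, smoothness, coarse = 8) {
  wc <- max(4, ceiling(dims[1] / coarse))
  hc <- max(4, ceiling(dims[2] / coarse))
  z <- matrix(rnorm(hc * wc), hc, wc)
  z <- cpp_gauss_blur(z, max(smoothness / coarse, 0.5))
  g <- grid_coords(dims[1], dims[2]) / coarse
  zc <- cpp_bspline_prefilter(z)
  matrix(cpp_interp(zc, pmin(g[, 1], wc - 1), pmin(g[, 2], hc - 1), 3L, 0),
         dims[2], dims[1])
}

#' Generate a synthetic H&E-like tissue slide
#'
#' White slide background, a smooth eosin-like texture and `n_nuclei` dark
#' elliptical nuclei with irregular borders placed without overlap. The
#' exact nucleus centers are returned — they are the ground-truth structures
#' whose coordinates the registration pipeline maps between slides.
#'
#' @param width,height base dimensions (>= 64).
#' @param n_nuclei number of nuclei (>= 0).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @param nucleus_radius mean nucleus semi-axis in px.
#' @return `list(image = h x w x 3 array, centers = n x 2 matrix (x, y),
#'   tissue = logical h x w mask)`.
#' @export
generate_tissue_slide <- function(width, height, n_nuclei = 150, seed = 1,
                                  nucleus_radius = 5) {
  if (width < 64 || height < 64) stop("slide dimensions must be >= 64")
  if (n_nuclei < 0) stop("n_nuclei must be >= 0")
  with_seed(seed, {
    # one irregular tissue fragment on a white slide: a wobbly ellipse
    # whose boundary radius is modulated by low-order harmonics
    cx0 <- (width - 1) / 2; cy0 <- (height - 1) / 2
    ax <- 0.40 * width; ay <- 0.40 * height
    wob <- runif(4, 0, 2 * pi)
    frag_rho <- function(x, y) {
      u <- (x - cx0) / ax; v <- (y - cy0) / ay
      psi <- atan2(v, u)
      sqrt(u^2 + v^2) /
        (1 + 0.14 * sin(2 * psi + wob[1]) + 0.10 * sin(3 * psi + wob[2]) +
           0.05 * sin(5 * psi + wob[3]))
    }
    gg <- grid_coords(width, height)
    tissue <- matrix(frag_rho(gg[, 1], gg[, 2]) <= 1, height, width)
    tex <- smooth_field(c(width, height), 24)
    tex <- (tex - min(tex)) / max(diff(range(tex)), 1e-12)
    # sparse eosin strands: emphasize the upper tail of the field
    tex <- tex^2
    tex[!tissue] <- 0
    r_ch <- 252 - 30 * tex; r_ch[!tissue] <- 255
    g_ch <- 240 - 90 * tex; g_ch[!tissue] <- 255
    b_ch <- 245 - 55 * tex; b_ch[!tissue] <- 255
    # faint eosin wash over the whole fragment so tissue != background
    g_ch[tissue] <- g_ch[tissue] - 14
    b_ch[tissue] <- b_ch[tissue] - 6
    img <- array(c(r_ch, g_ch, b_ch), c(height, width, 3))
    centers <- matrix(numeric(0), 0, 2)
    if (n_nuclei > 0) {
      min_sep <- 3.2 * nucleus_radius
      margin <- min(3 * nucleus_radius, min(width, height) %/% 8)
      tries <- 0
      while (nrow(centers) < n_nuclei && tries < 200 * n_nuclei + 10000) {
        tries <- tries + 1
        cand <- c(runif(1, margin, width - 1 - margin),
                  runif(1, margin, height - 1 - margin))
        if (frag_rho(cand[1], cand[2]) > 0.92) next
        if (nrow(centers) == 0 ||
            min(sqrt((centers[, 1] - cand[1])^2 +
                     (centers[, 2] - cand[2])^2)) >= min_sep)
          centers <- rbind(centers, cand)
      }
      if (nrow(centers) < n_nuclei)
        stop("could not place ", n_nuclei, " non-overlapping nuclei")
      for (i in seq_len(n_nuclei)) {
        a <- runif(1, 0.75, 1.25) * nucleus_radius
        b <- runif(1, 0.7, 1.0) * a
        phi <- runif(1, 0, pi)
        ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
        cx <- centers[i, 1]; cy <- centers[i, 2]
        ext <- ceiling(1.4 * a) + 1
        xs <- max(0, floor(cx - ext)):min(width - 1, ceiling(cx + ext))
        ys <- max(0, floor(cy - ext)):min(height - 1, ceiling(cy + ext))
        gx <- outer(rep(1, length(ys)), xs) - cx
        gy <- outer(ys, rep(1, length(xs))) - cy
        u <- gx * cos(phi) + gy * sin(phi)
        v <- -gx * sin(phi) + gy * cos(phi)
        rho <- sqrt((u / a)^2 + (v / b)^2)
        psi <- atan2(v, u)
        rim <- 1 + 0.14 * sin(3 * psi + ph1) + 0.09 * sin(5 * psi + ph2)
        inside <- rho <= rim
        shade <- 0.75 + 0.5 * pmin(rho / rim, 1)^2  # darker core
        col <- c(82, 58, 132)                        # hematoxylin purple
        for (k in 1:3) {
          layer <- img[ys + 1, xs + 1, k]
          layer[inside] <- (col[k] * shade[inside])
          img[ys + 1, xs + 1, k] <- layer
        }
      }
    }
    img[img < 0] <- 0; img[img > 255] <- 255
    dimnames(img) <- NULL
    rownames(centers) <- NULL
    list(image = img, centers = unname(centers), tissue = tissue)
  })
}

# exact forward point mapping fixed-base -> moving-base for a scenario
make_gt_map <- function(scenario, fixed_dims, moving_dims, sim, disp) {
  op <- scenario$orientation_op
  e <- scenario$extent_offset
  disp_at <- function(p) {
    if (is.null(disp)) return(p * 0)
    dx <- cpp_interp(disp$dx, p[, 1], p[, 2], 1L, 0)
    dy <- cpp_interp(disp$dy, p[, 1], p[, 2], 1L, 0)
    cbind(dx, dy)
  }
  map <- function(p) {
    vec <- is.null(dim(p))
    pm <- if (vec) matrix(as.numeric(p), 1, 2) else as.matrix(p)[, 1:2, drop = FALSE]
    p1 <- sweep(pm, 2, e)
    p2 <- apply_orientation_pretransform(p1, op, dims = fixed_dims)
    p3 <- transform_point(sim, p2)
    q <- p3 + disp_at(p3)
    if (vec) as.numeric(q) else unname(q)
  }
  inverse <- function(q) {
    vec <- is.null(dim(q))
    qm <- if (vec) matrix(as.numeric(q), 1, 2) else as.matrix(q)[, 1:2, drop = FALSE]
    p3 <- qm
    for (i in 1:4) p3 <- qm - disp_at(p3)
    p2 <- transform_point(invert_transform(sim), p3)
    od <- if (orientation_swaps_axes(op)) rev(fixed_dims) else fixed_dims
    p1 <- apply_orientation_pretransform(p2, orientation_inverse(op), dims = od)
    p <- sweep(p1, 2, e, `+`)
    if (vec) as.numeric(p) else unname(p)
  }
  structure(list(map = map, inverse = inverse, fixed_dims = fixed_dims,
                 moving_dims = moving_dims),
            class = "ground_truth_map")
}

#' @export
print.ground_truth_map <- function(x, ...) {
  cat(sprintf("<ground truth map  fixed %d x %d -> moving %d x %d>\n",
              x$fixed_dims[1], x$fixed_dims[2],
              x$moving_dims[1], x$moving_dims[2]))
  invisible(x)
}

#' Derive the re-stained, re-scanned moving slide of a scenario
#'
#' Resamples the fixed slide through the scenario's composed mapping,
#' re-stains it per the scenario's stain model, perturbs intensities, and
#' builds the moving pyramid. The returned ground-truth map gives the exact
#' moving-base coordinate of any fixed-base point; it depends only on the
#' scenario geometry, never on the stain model.
#'
#' @param fixed output of [generate_tissue_slide()] (or a compatible
#'   `list(image =, centers =)`).
#' @param scenario a [slide_scenario()].
#' @param mpp fixed-slide base mpp (micrometers per pixel).
#' @param magnification nominal magnification of both scans.
#' @param n_levels pyramid levels for the moving slide.
#' @return `list(pyramid, gt, scenario, centers_moving)`.
#' @export
derive_moving_slide <- function(fixed, scenario, mpp = 0.25,
                                magnification = 40, n_levels = 6) {
  stopifnot(inherits(scenario, "slide_scenario"))
  if (scenario$deform_amplitude > scenario$deform_smoothness / 2)
    stop("invalid scenario: deformation amplitude > smoothness / 2 would fold the tissue")
  img <- fixed$image
  H <- dim(img)[1]; W <- dim(img)[2]
  op <- scenario$orientation_op
  od <- if (orientation_swaps_axes(op)) c(H, W) else c(W, H)
  s_eff <- scenario$scale / scenario$mpp_ratio
  Wm <- ceiling(od[1] * s_eff); Hm <- ceiling(od[2] * s_eff)
  ctr <- c((od[1] - 1) / 2, (od[2] - 1) / 2)
  # similarity about the oriented frame center, recentered on the moving canvas
  ctr_m <- c((Wm - 1) / 2, (Hm - 1) / 2)
  sim <- similarity_transform(scenario$angle, s_eff,
                              ctr_m[1] - ctr[1] + scenario$tx,
                              ctr_m[2] - ctr[2] + scenario$ty,
                              center = ctr)
  with_seed(scenario$seed, {
    disp <- NULL
    if (scenario$deform_amplitude > 0) {
      dx <- smooth_field(c(Wm, Hm), scenario$deform_smoothness)
      dy <- smooth_field(c(Wm, Hm), scenario$deform_smoothness)
      mag <- sqrt(dx^2 + dy^2)
      sc <- scenario$deform_amplitude / max(mag, 1e-12)
      disp <- list(dx = dx * sc, dy = dy * sc)
    }
    gt <- make_gt_map(scenario, c(W, H), c(Wm, Hm), sim, disp)
    # backward warp: moving pixel -> fixed coordinate -> sample fixed RGB
    g <- grid_coords(Wm, Hm)
    p_fixed <- gt$inverse(g)
    mov <- array(0, c(Hm, Wm, 3))
    for (k in 1:3)
      mov[, , k] <- matrix(cpp_interp(img[, , k], p_fixed[, 1], p_fixed[, 2],
                                      1L, 255), Hm, Wm)
    centers_moving <- if (nrow(fixed$centers) > 0) gt$map(fixed$centers)
                      else fixed$centers
    if (scenario$stain_model == "ihc")
      mov <- restain_ihc(mov, centers_moving, s_eff * 5,
                         scenario$dab_fraction)
    if (scenario$noise_sigma > 0) {
      mov <- mov + array(rnorm(length(mov), 0, scenario$noise_sigma), dim(mov))
      mov[mov < 0] <- 0; mov[mov > 255] <- 255
    }
    pyr <- build_pyramid(mov, n_levels, mpp = mpp * scenario$mpp_ratio,
                         magnification = magnification)
    list(pyramid = pyr, gt = gt, scenario = scenario,
         centers_moving = centers_moving)
  })
}

# IHC-like appearance: keep hematoxylin-ish nuclei, fade the eosin texture
# to a pale counterstain, and add a DAB-brown ring around a nucleus subset
# (an antigen such as PHH3 labels only a minority of nuclei).
restain_ihc <- function(img, centers, ring_radius, dab_fraction) {
  lum <- to_gray(img)
  dark <- pmin(pmax((200 - lum) / 140, 0), 1)   # 1 inside nuclei, 0 on bg
  shade <- lum / 255
  texness <- pmin(pmax((252 - lum) / 60, 0), 1) # eosin-texture density
  out <- img
  # counterstain: blue-gray wash following the tissue texture so that the
  # fragment keeps visible contrast to the white slide background, nuclei
  # toward hematoxylin blue
  out[, , 1] <- (1 - dark) * (253 - 60 * texness) + dark * 95 * shade * 2.2
  out[, , 2] <- (1 - dark) * (253 - 48 * texness) + dark * 98 * shade * 2.2
  out[, , 3] <- (1 - dark) * (254 - 24 * texness) + dark * 165 * shade * 2.0
  if (nrow(centers) > 0 && dab_fraction > 0) {
    n_dab <- round(dab_fraction * nrow(centers))
    if (n_dab > 0) {
      idx <- sample.int(nrow(centers), n_dab)
      H <- dim(img)[1]; W <- dim(img)[2]
      for (i in idx) {
        cx <- centers[i, 1]; cy <- centers[i, 2]
        ext <- ceiling(ring_radius * 1.6)
        if (cx + ext < 0 || cx - ext > W - 1 || cy + ext < 0 || cy - ext > H - 1)
          next  # nucleus mapped outside the moving scan extent
        xs <- max(0, floor(cx - ext)):min(W - 1, ceiling(cx + ext))
        ys <- max(0, floor(cy - ext)):min(H - 1, ceiling(cy + ext))
        if (length(xs) < 2 || length(ys) < 2) next
        gx <- outer(rep(1, length(ys)), xs) - cx
        gy <- outer(ys, rep(1, length(xs))) - cy
        r <- sqrt(gx^2 + gy^2)
        ring <- abs(r - ring_radius) < ring_radius * 0.35
        dab <- c(140, 88, 38)
        for (k in 1:3) {
          layer <- out[ys + 1, xs + 1, k]
          layer[ring] <- 0.35 * layer[ring] + 0.65 * dab[k]
          out[ys + 1, xs + 1, k] <- layer
        }
      }
    }
  }
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

#' Generate point annotations on a slide
#'
#' Clustered mode samples uniformly within `region`; sparse mode enforces a
#' minimum pairwise distance by rejection sampling (erroring out after a
#' bounded number of proposals when the packing is infeasible).
#'
#' @param n number of points (>= 1).
#' @param mode `"clustered"` or `"sparse"`.
#' @param region a [wsi_rect()] to sample within.
#' @param seed RNG seed.
#' @param min_distance minimum pairwise distance for sparse mode (default
#'   2048, one refinement tile).
#' @return Data frame with columns `id`, `x`, `y`.
#' @export
generate_annotations <- function(n, mode = c("clustered", "sparse"), region,
                                 seed = 1, min_distance = 2048) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, inherits(region, "wsi_rect"))
  with_seed(seed, {
    if (mode == "clustered") {
      x <- runif(n, region$x, region$x + region$w)
      y <- runif(n, region$y, region$y + region$h)
      return(data.frame(id = seq_len(n), x = x, y = y))
    }
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0
    limit <- 10000 + 500 * n
    while (nrow(pts) < n && tries < limit) {
      tries <- tries + 1
      cand <- c(runif(1, region$x, region$x + region$w),
                runif(1, region$y, region$y + region$h))
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
            min_distance)
        pts <- rbind(pts, cand)
    }
    if (nrow(pts) < n)
      stop("sparse packing infeasible: placed ", nrow(pts), " of ", n,
           " points at min distance ", min_distance)
    data.frame(id = seq_len(n), x = unname(pts[, 1]), y = unname(pts[, 2]))
  })
}
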