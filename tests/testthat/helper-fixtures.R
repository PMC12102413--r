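# Shared fixtures, built once per test run and memoized. All fixtures are
# generated in code — nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small H&E-like slide (matrix form used by metric / register tests)
small_slide <- function() fixture("small_slide", function() {
  generate_tissue_slide(256, 256, n_nuclei = 30, seed = 5)
})

small_gray <- function() to_gray(small_slide()$image)

# a mid-size fixed pyramid + similarity-only moving pair with ground truth
sim_pair <- function() fixture("sim_pair", function() {
  sl <- generate_tissue_slide(512, 512, n_nuclei = 90, seed = 11)
  fixed <- build_pyramid(sl$image, 5, mpp = 0.25, magnification = 20)
  sc <- slide_scenario(angle = 8, scale = 1.04, tx = 18, ty = -12, seed = 21)
  mv <- derive_moving_slide(sl, sc, mpp = 0.25, magnification = 20,
                            n_levels = 5)
  list(slide = sl, fixed = fixed, moving = mv, scenario = sc)
})

# dense joint-histogram mutual information oracle: an independent plain-R
# implementation of the Parzen-window MI definition (box kernel on the
# fixed intensities, cubic B-spline kernel on the moving intensities)
bspline3_ref <- function(t) {
  t <- abs(t)
  ifelse(t < 1, (4 - 6 * t^2 + 3 * t^3) / 6,
         ifelse(t < 2, (2 - t)^3 / 6, 0))
}

mi_dense_oracle <- function(f, m, nbins = 32) {
  fr <- range(f); mr <- range(m)
  bwf <- diff(fr) / nbins; bwm <- diff(mr) / nbins
  bf <- pmin(pmax(floor((as.vector(f) - fr[1]) / bwf), 0), nbins - 1)
  u <- (as.vector(m) - mr[1]) / bwm - 0.5
  J <- matrix(0, nbins, nbins)
  for (d in -1:2) {
    j <- floor(u) + d
    w <- bspline3_ref(u - j)
    j <- pmin(pmax(j, 0), nbins - 1)
    for (k in which(w > 0))
      J[bf[k] + 1, j[k] + 1] <- J[bf[k] + 1, j[k] + 1] + w[k]
  }
  P <- J / sum(J)
  pf <- rowSums(P); pm <- colSums(P)
  idx <- P > 0
  sum(P[idx] * log(P[idx] / outer(pf, pm)[idx]))
}

# centroids of dark blobs (nuclei) detected with EBImage; the detection
# oracle used to check generator geometry
detect_nucleus_centroids <- function(img, threshold = 150) {
  gray <- to_gray(img)
  mask <- gray < threshold
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
  n <- max(lab)
  if (n == 0) return(matrix(numeric(0), 0, 2))
  idx <- which(lab > 0, arr.ind = TRUE)
  id <- lab[lab > 0]
  area <- tabulate(id, n)
  cx <- rowsum(idx[, 2] - 1, id)[, 1] / area
  cy <- rowsum(idx[, 1] - 1, id)[, 1] / area
  cbind(cx, cy)
}

# match each truth point to its nearest detected centroid
nearest_dist <- function(truth, detected) {
  vapply(seq_len(nrow(truth)), function(i) {
    min(sqrt((detected[, 1] - truth[i, 1])^2 +
               (detected[, 2] - truth[i, 2])^2))
  }, numeric(1))
}

# a fitted Strategy-I registration on the similarity pair (chain reuse,
# decoupling and acceptance tests share it)
strategy1_fit <- function() fixture("strategy1_fit", function() {
  pr <- sim_pair()
  ann <- generate_annotations(15, "clustered", wsi_rect(160, 160, 192, 192),
                              seed = 4)
  fit <- register_slides(pr$fixed, pr$moving$pyramid, ann, strategy = "1",
                         tile_size = 160,
                         refine_config = reg_config(n_resolutions = 1,
                                                    iterations = 150,
                                                    n_samples = 1024),
                         seed = 12)
  list(fit = fit, ann = ann)
})
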