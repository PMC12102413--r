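---
title: "Hierarchical point colocalization between re-stained whole slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical point colocalization between re-stained whole slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsicoloc)
```

## The problem

A histological section is stained with H&E, scanned, then chemically
de-stained, re-stained with an immunohistochemical marker (for instance
PHH3, which labels mitotic figures with brown DAB chromogen) and scanned
again — possibly on a different scanner. Annotations made on one whole
slide image (WSI), such as mitosis coordinates, must be transferred to the
other scan of the *same physical tissue*. This is colocalization, not
classical image registration: the deliverable is a mapping for point
coordinates, not a warped image. Because the tissue is identical (unlike
consecutive sections), sub-micrometer accuracy is attainable — but the two
scans differ in stain appearance, intensity profile, resolution (mpp can
differ by ~10–20 % even at "the same" magnification), scanned extent,
orientation, and by small local deformations introduced by the re-staining
chemistry.

`wsicoloc` implements this as a fitted-model workflow: `register_slides()`
estimates a hierarchical chain of transforms; `predict()` maps point sets
through it.

## The model

### Coarse stage

Tissue is first segmented on overview pyramid levels (Otsu threshold on
luminance, dilation, erosion, hole filling; particles filtered by area
`>= mean - k_a*sd` and by centroid distance from the area-weighted mass
center `<= mean + k_d*sd`, iterated to a fixed point so the filter is
idempotent, with a never-empty fallback to the largest particle). The
overview level is chosen so the effective magnification is ~2.5x: level 5
for an 80x scan, level 4 for 40x, clamped to the available levels. The two
ROI crops are then registered with a **similarity transform**
(`p -> s R(theta) (p - c) + c + t`, four free parameters; the rotation
center `c` is the ROI crop's geometric center and the moving image is
initialized at the geometric center of the fixed image).

The similarity metric is **Mattes mutual information**: the joint intensity
density is estimated with Parzen windows — a zero-order (box) kernel over
the fixed-image intensities and a cubic B-spline kernel over the moving
intensities — from randomly sampled fixed-domain coordinates. MI is
invariant to intensity relabeling, which is what makes registration across
stains possible; the test suite checks `MI(f, 255 - f) = MI(f, f)` exactly
and checks the sampled estimator against an independent dense
joint-histogram oracle to 1e-6 nats.

Optimization is **adaptive stochastic gradient descent**:
`x_{k+1} = x_k - gamma(t_k) g_k` with `gamma(t) = a / (A + t)^alpha`, where
the artificial time `t` advances by a sigmoid of the inner product of
successive gradients — oscillating gradients shrink the step, correlated
gradients keep it large. Gradients are central finite differences on the
sampled metric with a common sample set per iteration (common random
numbers). Two numerical safeguards matter in practice: `a` is auto-scaled
so the first step moves points by about `step_target` (1 px), and a trust
region caps any step at `max_step` (5 px) of induced motion — without the
cap a noisy first gradient on a small overview can produce a divergent
schedule. Heterogeneous parameters (degrees, scale, pixels) are optimized
in a scaled space where one unit of any parameter moves the ROI corner by
about one pixel.

The driver is multi-resolution (Gaussian pyramids, coarse to fine).
Parameters are always expressed in the frame of the input images and sample
coordinates are rescaled per level, so no between-level parameter
conversion can be forgotten — the classic double-scaling bug in
hierarchical registration is structurally excluded; the only place scale
conversion happens is `extrapolate_to_base()`, which lifts the overview
transform to base-layer coordinates in closed form (angle and scale
unchanged, translations, center and ROI offsets scaled by the level
factors).

### Refinement strategies

The extrapolated transform is accurate to roughly the overview pixel
(tested: mean error at most twice the overview downsample factor). Two
base-layer refinements sharpen it:

* **Strategy I (grid tiles)** — for spatially clustered annotations. The
  fixed ROI is tiled row-major with equal square tiles (default 2048 px;
  scaled-down suites use 160–256 px); only tiles containing annotations are
  registered. The moving counterpart of each tile is extracted through the
  coarse transform (bounding-box read, then inverse warp that compensates
  rotation *and* scale, cubic B-spline interpolation) and registered
  rigidly with a reduced budget. A tile that fails keeps the coarse
  transform — no point is ever lost.
* **Strategy II (per-annotation patches)** — for sparse annotations. A
  square patch (64–1024 px, default 192, the middle of the recommended
  128–256 range) is read around each annotation and around its
  coarse-mapped location (again rotation/scale-compensated), and an affine
  correction is estimated per annotation. Patches that would leave either
  slide are flagged and keep the coarse coordinate.

The advisory `choose_strategy()` compares `occupied_tiles * tile_px^2`
against `n_points * patch_px^2 * 4`; the factor 4 reflects that per-point
registration pays a fixed overhead per annotation while tile registration
amortizes it, consistent with the relative per-pixel throughputs implied by
published timing tables for the two strategies.

When the two scans have different magnifications, the base layer of the
lower-resolution slide is the reference and the mpp-matched level of the
other pyramid is used for refinement reads.

### Transform chains

Registration and transformation are decoupled. A `transform_chain` stores
the steps strictly in creation order: the base similarity, then per-tile or
per-point corrections, then (if configured) the inverse orientation op
mapping back into the moving scan's native frame. Corrections are stored as
the base-transform conjugate, i.e. as moving-domain transforms, so
successive application reproduces base-then-refinement composition exactly
while domains (tile rects, annotation ids) are resolved against the
original fixed coordinates. Chains serialize to versioned JSON at full
double precision and reload bit-exactly; Strategy-I chains map arbitrary
new point sets without re-registration, Strategy-II chains refuse unseen
annotation ids because their corrections are per-annotation.

Final coordinates are discretized by round-half-to-even; the discretization
error is at most 0.5 px per coordinate by construction. The optional
`smooth = TRUE` mode interpolates the per-tile displacement samples (taken
at tile centers) with a separable cubic B-spline across the grid instead of
applying tiles piecewise; tiles are treated independently by default
because nothing in the tile estimates guarantees that smoothing across
boundaries is closer to the truth.

### Evaluation

Real slide pairs have no pixel-precise ground truth at nucleus scale
(pixel-precise nucleus segmentation is not achievable, which also rules out
TRE/Jaccard/Dice at this scale), so alignment is scored with **SSIM**:
patches of a fixed physical size are extracted around the mapped
coordinates on every slide, rescaled to the pixel dimensions of the slide
with the lowest resolution (largest mpp), cropped by their first and last
rows and columns (guarding against off-by-one dimensions after rescaling),
and compared pairwise on luminance; each annotation is summarized by its
minimum SSIM over all pairs. SSIM uses a Gaussian window (width 11, sigma
1.5) and constants K1 = 0.01, K2 = 0.03 on the declared dynamic range —
the standard choices, exposed in the arguments since they are conventions,
not physics.

Synthetic pairs additionally allow exact per-point error
(`colocalization_error()`, reported in px and µm).

## The synthetic-data generator

`generate_tissue_slide()` renders one irregular tissue fragment (a wobbly
ellipse) on a white slide: a smooth eosin-like texture plus dark elliptical
nuclei with irregular borders, placed without overlap, with exact centers
returned. `derive_moving_slide()` applies a `slide_scenario()`: extent
offset, one of the eight dihedral orientation ops, a global similarity
(about the oriented frame's center, with the mpp ratio folded into the
scale), and a smooth random displacement field applied in the moving
domain — in that fixed composition order, mirroring the pipeline's
compensation order. The ground-truth map is closed-form (the deformation
term is inverted numerically; amplitudes above `smoothness / 2` are
rejected as folding). Re-staining is emulated by an IHC appearance model:
pale blue-gray counterstain, hematoxylin-like nuclei, and DAB-brown rings
on a random 30 % nucleus subset (an IHC marker labels a minority of
nuclei). Stain and noise never touch the geometry: the ground-truth map is
identical for both stain models by construction, and the tests assert it.

Defaults are the study conditions the generator is meant to emulate:
misalignment angles up to ±15°, scale 0.95–1.1 (scanner mpp differences of
~10–20 % fold into this), translations up to ~±70 px at the 1024² study
scale, deformation amplitude 1.5 px with 200 px smoothness for re-staining
damage, intensity noise sigma 2. Deformation magnitudes for re-staining
damage are not quantified anywhere we know of; 1.5 px at 0.25 mpp (≈0.4 µm)
is a plausible stand-in for "minor tears and deformations" and is exposed
as a parameter. What the generator does *not* emulate: real stain chemistry
and color deconvolution, tears/folds that break invertibility, out-of-focus
regions, scanner compression artifacts, anisotropic mpp (supported as
metadata only). Passing tests therefore demonstrate the pipeline's
geometric correctness and its robustness to appearance change and smooth
deformation — not robustness to every failure mode of clinical scans.

## Problem sizes and budgets

The package's test and acceptance runs use desk-scale study conditions
chosen once: 1024² synthetic slides (0.25 mpp declared) for the coarse
parameter-recovery and sub-micrometer suites, 512² pairs for property
suites, 100 annotations in a compact region for Strategy I and the same
count for Strategy II, tile 256 px and patch 192 px at that scale, coarse
budgets of 3 resolutions x 500 iterations x 2048 samples and refinement
budgets of 1–2 resolutions x 250 iterations x 1024 samples. On these
conditions the full pipeline achieves mean colocalization error well below
1 µm and median below 0.5 µm for both strategies, and the coarse stage
recovers similarity parameters within 0.5° / 0.01 / 2 overview px on at
least 9 of 10 seeds — the quantities the acceptance suite recomputes.

## Numerical choices

* Cubic B-spline interpolation everywhere a continuous sample is needed
  (metric, resampling, rotated-region extraction, patch rescaling), with
  the standard recursive prefilter so interpolation is exact at pixel
  centers; mirror boundaries.
* Pyramid construction: Gaussian anti-aliasing with sigma = 2/3 per 2x
  halving; level dims follow `ceiling(previous / 2)`.
* Angle convention: degrees, counter-clockwise positive in the y-down pixel
  frame; 0-based pixel coordinates with centers at integers; rects are
  half-open. Stated once, used everywhere, serialized into every chain.
* MI bins: 32; histogram mass falling outside the first/last moving bins is
  accumulated on the edge bins so the joint density always sums to one.
* Degenerate inputs: constant images give MI = 0 with a warning; transforms
  mapping fewer than 25 % of samples into the moving image raise an overlap
  error; failed tiles/points fall back to the coarse transform with status
  recorded.
* Tie-breaks: annotations on tile boundaries belong to the lower row-major
  tile index (half-open rects make this deterministic).

## Known limitations

Non-rigid (B-spline deformation) models are out of scope — per-tile and
per-point *linear* corrections approximate smooth deformation locally,
which is exactly why residuals grow from tile centers toward corners (a
property the tests check). Automatic detection of right-angle rotations and
flips is not attempted; they are runtime parameters. Proprietary scanner
formats are not parsed; plain multi-page TIFF plus a JSON sidecar is the
exchange format, and anything else must be converted or plugged in through
the same reader interface. The segmentation is deliberately naive (Otsu +
morphology) and has a manual ROI override because it will fail on slides
with faint tissue, pen marks or heavy artifacts.
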