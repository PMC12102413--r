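# wsicoloc

Hierarchical, stain- and scanner-independent **point colocalization**
between whole slide images (WSIs).

When a histological section is stained with H&E, scanned, then re-stained
with an immunohistochemical marker (e.g. PHH3 for mitoses) and re-scanned —
possibly on a different scanner — annotations made on one scan must be
transferred to the other. The two scans show the *same physical tissue*,
but differ in stain appearance, intensity, resolution (mpp), scanned
extent, orientation, and by small local deformations from the re-staining
chemistry. `wsicoloc` maps point annotations (nucleus / mitosis
coordinates) from one such WSI into the other with sub-micrometer accuracy.
It computes point mappings, not warped images.

## Method

For a fixed image $I_F$ and moving image $I_M$, the package estimates an
ordered chain of transforms, refined from macroscopic to microscopic scale:

1. **Preprocessing** — tissue segmentation on overview levels (Otsu
   threshold + morphology, particle relevance filter with a manual ROI
   override), configured orientation pre-transforms (the eight dihedral
   ops).
2. **Coarse registration** — a similarity transform
   $T(p) = s\,R(\theta)(p - c) + c + t$ (four free parameters; $c$ is the
   ROI center) on overview levels chosen so the effective magnification is
   about 2.5x (80x scan → level 5, 40x → level 4). The metric is Mattes
   mutual information with Parzen windows (box kernel on fixed, cubic
   B-spline kernel on moving intensities) over random coordinate samples;
   the optimizer is adaptive stochastic gradient descent with step size
   $\gamma(t) = a/(A+t)^\alpha$ and gradient-correlation time adaptation.
   The overview transform is then extrapolated in closed form to base-layer
   coordinates.
3. **Refinement** — either **Strategy I** (a row-major grid of equal tiles
   over the ROI, each tile registered rigidly against its
   rotation/scale-compensated moving counterpart; suited to spatially
   clustered annotations, and the resulting chain is reusable for arbitrary
   new point sets) or **Strategy II** (a small square patch, 128–256 px,
   centered on every single annotation, corrected with an affine model;
   suited to sparse annotations).
4. **Transformation** — the chain is applied to point sets in creation
   order, with cubic B-spline interpolation options for the tile
   displacement field, and round-half-to-even discretization. Registration
   and transformation are decoupled: chains serialize to JSON and reload
   bit-exactly.
5. **Evaluation** — SSIM of patches centered on mapped coordinates,
   rescaled to the coarsest scanner's patch dimensions and cropped by their
   first/last rows and columns; per-annotation minimum SSIM across slide
   pairs. Synthetic pairs also report exact per-point error in px and µm.

A synthetic-data module generates re-stained/re-scanned pairs (H&E-like and
IHC-like appearance, mpp differences, orientation changes, extent offsets,
smooth local deformation, noise) with **exact ground-truth point
correspondences** for validation.

## Worked example

Fit a registration on a synthetic re-stained pair and map annotations:

```r
library(wsicoloc)

sl <- generate_tissue_slide(512, 512, n_nuclei = 90, seed = 11)
fixed <- build_pyramid(sl$image, 5, mpp = 0.25, magnification = 20)
scenario <- slide_scenario(angle = 8, scale = 1.04, tx = 18, ty = -12,
                           stain_model = "ihc", deform_amplitude = 1.5,
                           noise_sigma = 2, seed = 21)
moving <- derive_moving_slide(sl, scenario, mpp = 0.25, magnification = 20,
                              n_levels = 5)
annotations <- generate_annotations(50, "clustered",
                                    wsi_rect(176, 176, 160, 160), seed = 4)

fit <- register_slides(fixed, moving$pyramid, annotations, strategy = "1",
                       tile_size = 160,
                       refine_config = reg_config(n_resolutions = 1,
                                                  iterations = 250,
                                                  n_samples = 1024),
                       seed = 12)
print(fit)
#> Whole-slide registration for point colocalization
#>   strategy: 1   coarse levels: (3, 3)   seed: 12
#>   base transform: <similarity transform  angle = 7.8586 deg  scale = 1.04183  t = (30.731, -2.711)  c = (260.0, 244.0)>
#>   refinement: 2 tile(s) (2 ok, 0 failed), 0.05 million registered
```

The fitted base transform recovers the scenario's misalignment (8° and
scale 1.04 were simulated; 7.86° and 1.0418 were estimated — the residual
is absorbed by the per-tile corrections). `predict()` maps the annotations
into the moving slide's base coordinates:

```r
head(predict(fit), 3)
#>   id   x   y flag
#> 1  1 297 234   ok
#> 2  2 210 306   ok
#> 3  3 260 324   ok
```

Because the pair is synthetic, the exact target coordinates are known and
the colocalization error can be measured directly:

```r
truth <- moving$gt$map(cbind(annotations$x, annotations$y))
colocalization_error(predict(fit),
                     data.frame(id = annotations$id,
                                x = truth[, 1], y = truth[, 2]),
                     mpp = 0.25)
#> <colocalization error  n = 50  mean 0.140 um  median 0.130 um  max 0.325 um>
```

A mean error of 0.14 µm at 0.25 µm/px is about half a pixel — every
annotation lands on the correct nucleus. `write_chain(fit$chain, path)`
stores the transform chain; `reuse_chain()` (or `predict(fit, newdata)`)
maps further point sets without re-registration for Strategy-I chains.

A command-line front end with `synthesize`, `segment`, `register`,
`transform`, `evaluate` and `run` subcommands is installed at
`inst/cli/wsicoloc.R`; see `vignettes/methods.Rmd` for the model, its
assumptions, parameter defaults and limitations.

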