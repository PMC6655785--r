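---
title: "Registering re-stained whole-slide image pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering re-stained whole-slide image pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidealign)
```

## The problem

When a stained tissue section is scanned, washed, re-stained and scanned
again — typically H&E first, then an immunohistochemical (IHC) marker — the
two whole-slide images (WSIs) show the *same cells* in different colours.
Comparing features at the sub-cellular level requires overlaying the two
gigapixel images precisely. Because the tissue never leaves the glass, the
misalignment between the scans is essentially a rigid translation with at
most a very small rotation; no deformable model is appropriate, and a
deformable fit would in fact invent correspondences that do not exist.

Direct registration at full resolution fails surprisingly often: H&E stains
both nuclei and cytoplasm densely while IHC highlights only the marked
protein, so local texture differs, and many patches (fat, lumen, sparse
stroma) carry too little structure to register at all. `slidealign`
implements a three-stage strategy that embraces these failures instead of
trying to avoid them:

1. **Patch-based Fourier registration.** Patches are sampled from the
   low-resolution pyramid levels, where structure is visible to both
   stains, and each fixed/floating patch pair is registered by phase
   correlation: the cross-power spectrum
   $F_1^{*} F_2 / |F_1^{*} F_2|$ inverse-transforms to an impulse at the
   displacement between the patches.
2. **Kernel-density weighting.** All patch offsets from all levels are
   pooled (after scaling to the level-0 frame) and each offset is assigned
   the value of a bivariate Gaussian kernel density estimate at its own
   position, normalised to $[0,1]$. Offsets consistent with the consensus
   get weights near 1; stray registrations are down-weighted smoothly.
   Similarity scores are *not* trusted: on re-stained material a confident
   similarity score is no evidence of a correct offset.
3. **Hierarchical regression.** Pyramid levels are linked by exact integer
   downsample factors, so every correctly scaled offset must lie on one
   line through the origin. The slope is fitted by weighted least squares
   through the origin, and the final level-0 offset is the weighted mean of
   the offsets projected onto that direction.

## Model and estimators

A floating image that is a shifted replica of the fixed image,
$f_2(x,y) = f_1(x - \Delta x, y - \Delta y)$, has Fourier transform
$F_2 = e^{-j 2\pi(\xi \Delta x + \eta \Delta y)} F_1$; the normalised
cross-power spectrum therefore isolates exactly the phase ramp of the shift,
and its inverse transform peaks at $(\Delta x, \Delta y)$. The
implementation removes the mean, applies a Hann taper (suppressing
wrap-around edge artefacts), whitens with a guard of
$10^{-15}\max|F_1^{*}F_2|$ against zero spectral magnitude, maps the peak
into the signed interval $[-N/2, N/2)$, and refines it by evaluating the
correlation surface on locally upsampled grids via direct DFT sums (two
zoom stages, final step $2\times10^{-3}$ px). The upsampled-DFT refinement
was chosen over the common three-point parabola because parabola fits carry
a systematic bias of a few hundredths of a pixel; extrapolation to level 0
multiplies patch-level errors by the downsample factor (up to 32 here), so
that bias alone would exceed the sub-0.1-px behaviour the noise-free tests
demonstrate.

The correlation peak height, clipped to $[0,1]$, is reported as the score.
A patch registration is counted a success only if the score clears both the
configured floor (default 0.05) and a size-dependent noise ceiling
$2.5\sqrt{2\ln N / N}$ for $N$ pixels — the scale of the largest peak two
*unrelated* images of that size produce, estimated from the extreme-value
behaviour of the correlation surface. Texture-poor patches therefore fail
cleanly at any patch size. Failed patches stay in the pool but are excluded
from the KDE by default (`kde_include_failures` reverses this).

For the KDE stage, with $n$ pooled offsets $(X_i, Y_i)$ the density at a
point is

$$\hat f(x,y) = \frac{1}{n\,2\pi\,|H|^{1/2}}
  \sum_{i=1}^{n} \exp\!\Big(-\tfrac12\, d_i^{\top} H^{-1} d_i\Big),
  \qquad d_i = (x - X_i,\; y - Y_i)^{\top},$$

with bandwidth matrix $H = h^2 \hat\Sigma$, where $h = n^{-1/(d+4)}$ is
Scott's factor ($d = 2$) and $\hat\Sigma$ the sample covariance of the
offsets. The same dimensionless factor is used on both axes; a
diagonal-bandwidth variant $h^2\hat\sigma^2 I$ is available
(`kde_diagonal = TRUE`). Degenerate pools — a single sample, or all samples
identical — carry no disagreement to resolve and receive uniform weight 1.
Collinear pools are regularised with a small ridge so $H$ stays positive
definite. When rotation estimation is enabled, a separable 1-D KDE over the
angles multiplies into the weight; rotation is near zero and weakly coupled
to translation in the re-staining regime, so a joint 3-D KDE would spend
data on a coupling that is not there.

For the regression stage, an offset $(dx, dy)$ measured at a level with
downsample $D$ corresponds to $(D\,dx, D\,dy)$ level-0 pixels. The
cross-level slope $m$ minimises

$$c(m) = \sum_{l}\sum_{i} R_l\, \hat f(x_{il}, y_{il})\, (y_{il} - m x_{il})^2,$$

giving the closed form $m = \sum w x y / \sum w x^2$ with
$w = R_l \hat f$. $R_l$ is the resolution ratio of level $l$ to its
next-higher-resolution neighbour — $\{0.25, 0.25, 0.5\}$ for the three
sampled levels of a 1:4:16:32 pyramid, derived generically for any other
layout. A cost linear in the residual would be unbounded below and cannot
be minimised; the squared residual is the standard weighted-least-squares
reading of a "minimize the weighted residual" objective and is what the
implementation uses.

The fitted line constrains only the *direction* of the offset, so a point
estimate is still needed. The default (`regression = "projection"`)
projects every weighted offset onto the unit vector along $(1, m)$ and
takes the weighted mean position along it; this uses $m$ exactly as a
direction constraint and reduces to the plain weighted mean when the
samples are collinear. The simpler alternative that ignores $m$ entirely is
available as `regression = "weighted_mean"` for comparison. When the true
shift is nearly vertical the fit of $y$ on $x$ is ill-posed; the axis with
the larger weighted second moment is used as the abscissa and the fitted
slope inverted afterwards. KDE weighting is applied after pooling all
levels in the level-0 frame, so one density describes the consensus;
per-level densities (the subscript-$l$ reading of the cost above) are
available with `kde_pooled = FALSE`.

Before any patch work, the two slide thumbnails are phase-correlated and
the result scaled to level 0. This initial offset pre-shifts every
floating-patch read, so the per-patch correlations resolve only a small
residual — keeping residuals far from the $\pm N/2$ wrap-around boundary
even for large global shifts. If thumbnail registration itself fails
(score below floor), a zero initial offset is used with a warning.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `patch_size` | 256 | level-local px | Clamped to the level dimensions. 256 keeps patches meaningful on the small low-resolution planes of a 4-level pyramid while offering enough texture; with 512-px patches the lowest-resolution plane of a 1:4:16:32 pyramid under ~16k px would not fit a single patch. |
| `patches_per_level` | 30 | count | Sampling without replacement; fewer candidates than requested produces all candidates plus a warning. |
| `levels` | lowest-resolution three | — | The levels where the two stains still look alike. |
| `score_floor` | 0.05 | — | Combined with the size-dependent noise ceiling above. |
| `rotation` | off | — | Re-stained slides keep their position on the glass; enable for ±`max_rotation` (5°) log-polar search. |
| `weighting` | `"kde"` | — | `"score"` and `"uniform"` exist for comparison runs. |
| `seed` | 1 | — | Fully determines patch sampling; each level draws from its own `(seed, level)` stream so changing one level's request does not perturb another's. |

Tissue is located by brightness thresholding of the thumbnail: glass is
near-white, tissue darker, and the histogram strongly bimodal, so Otsu's
criterion chooses the threshold (`"auto"`); a fixed fallback of 220/255
covers degenerate all-tissue or all-glass thumbnails. Components smaller
than 0.1% of the thumbnail are dropped as debris. Patch footprints must lie
at least half inside the mask.

## The synthetic generator

No public corpus of re-stained WSI pairs with ground truth exists, so the
package ships a generator ([synthetic_spec()], [generate_pair()],
[generate_cohort()]) that renders one shared cell field twice: H&E-like
(purple elliptical nuclei, textured pink cytoplasm) and IHC-like (pale
counterstain, strong DAB brown on a random positive fraction of the *same*
nuclei). The ground-truth transform is applied to the floating rendition in
the continuous field — nucleus centres are moved analytically and the
value-noise texture layers are evaluated at inverse-mapped coordinates — so
subpixel truths are exact rather than limited by raster resampling. Blank
texture-poor regions (rendered at a scale large enough to engulf whole
patches) provoke genuine registration failures, and i.i.d. Gaussian noise
is added per scan. Pyramids are built by block averaging and written as
multi-page TIFF; identical spec and seed give byte-identical files.

Defaults: a four-level 1:4:16:32 pyramid, 2 nuclei per $10^4$ px² of
tissue (a plausible nuclear density at 0.25 µm/px), 65% tissue coverage,
20% blank tissue, noise σ = 5/255, 20% DAB-positive nuclei.

What the generator does *not* emulate: stain deconvolution physics,
chromatic aberration, scanner stitching seams, focus variation, tissue
folds, and any true deformation. Passing the test suite therefore shows
that the estimator chain is correct and robust under controlled, rigid,
known-truth conditions — it does not certify performance on a particular
scanner's output, where an initial visual check of the thumbnail overlay
remains good practice.

Problem sizes used by the tests and the acceptance script — 512² fixtures
for unit work, a 4096² noise-free pair, one 8192² pair for the full
pipeline, and 100-seed simulated offset pools — were chosen as the smallest
sizes at which all four pyramid levels of the canonical layout remain
meaningfully populated.

## Numerical choices and edge cases

* Shifts are mapped into $[-N/2, N/2)$; the thumbnail pre-shift keeps true
  residuals well inside.
* Out-of-slide patch reads pad with white (blank glass) and set a flag
  instead of erroring, so sampling near tissue edges cannot crash a run.
* A pool with *no* successful registrations falls back to the initial
  thumbnail offset with `quality = "degraded"` (distinct CLI exit code).
* All-zero residual pools (the initial offset already aligns the pair)
  short-circuit the slope fit with $m = 0$ and a zero projection.
* The KDE normalisation constant cancels in the weights (they are ratios
  to the maximum), so the estimator's absolute scale only matters for the
  density diagnostics, where the standard bivariate normal constant is
  used.

## Worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(level0_size = c(2048, 2048), true_dx0 = 96,
                       true_dy0 = -64, seed = 11)
paths <- generate_pair(spec, tempdir())

fit <- register_slides(paths$fixed, paths$floating, reg_config(seed = 5))
glance(fit)
evaluate_error(fit, c(96, -64))
autoplot(fit)   # offsets coloured by KDE weight, fitted direction, estimate
```

## Limitations

* Rigid translation (+ optional small rotation) only: serial sections need
  deformable registration, which is out of scope by design.
* The similarity score has no universal definition across registration
  back-ends; the correlation-peak definition here is a package choice.
* Keypoint detection is not implemented; [filter_matches_by_slope()]
  refines *any* matcher's output by the parallelism criterion but expects
  the matches from outside.
* Very small pyramids (lowest level under the patch size) degenerate to
  one whole-plane patch per level; the KDE then leans on the richer levels.
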