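---
title: "Uniform feature-space selection of vessel images for annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uniform feature-space selection of vessel images for annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselect)
```

## Motivation and model

Large collections of fluorescence-microscopy images of vasculature are cheap
to acquire and expensive to annotate. When only a small subset can be
annotated, the choice of subset determines what a downstream segmentation
model can learn: sampling in proportion to the data density under-represents
atypical imaging conditions, and models trained on such subsets fail exactly
where robustness matters. `vesselect` treats subset selection as a coverage
problem in a low-dimensional morphometry feature space rather than a sampling
problem in data space.

The procedure has three stages.

**1. Mapping.** Every candidate patch (an intensity image plus a binary vessel
mask, which may come from a semi-automatic segmentation) is described by four
features chosen to capture the axes along which vascular images vary most:

- *Contrast* `C = Iv / If`: ratio of mean vessel intensity to mean background
  intensity. Dimensionless; invariant to global intensity scaling.
- *Noise sigma*: the standard deviation of additive Gaussian noise, estimated
  robustly from the wavelet domain. We apply a single-level orthonormal Haar
  transform and take `sigma = median(|d|) / 0.6745` over diagonal detail
  coefficients whose entire 2x2 support lies in the background, so vessel
  edges cannot inflate the estimate. Intensity units.
- *Density*: total skeleton arc length divided by image area (units 1/px).
  The skeleton is a one-pixel 8-connected medial line; arc length sums 1 per
  axis-aligned adjacency and `sqrt(2)` per diagonal adjacency, the standard
  discrete approximation.
- *Medial-line heterogeneity* `h~`: intensity variability along the vessel
  lumen. The image is blurred with a unit-sigma Gaussian, the population
  standard deviation `h` and mean `m` of the blurred values at skeleton pixels
  are recorded, and because `h` grows with vessel brightness, an OLS line
  `h_m = a*m + b` fitted across the whole collection is subtracted:
  `h~ = h - h_m`. Residuals sum to zero by construction; if all `m` coincide
  the fit degenerates to slope 0, intercept `mean(h)`, and is flagged.

**2. Discretization and the sampling set.** The feature matrix is z-scored
(population variance) and snapped to a regular grid by flooring against a
per-axis cell width. The grid deliberately collapses many samples into one
cell — that collapsing is what makes uniform sampling of *cells* different
from uniform sampling of *samples*. A discrete hypersphere (closed Euclidean
ball) of radius `r` grid units is centered on every occupied cell and the
union forms the sampling set, a dilated estimate of the support of the
feature distribution that also covers plausible nearby feature combinations.

**3. Selection.** Points are drawn uniformly from the sampling set; each is
mapped to the nearest data sample in grid coordinates (ties to the lowest
index) and accepted unless it repeats a sample or a source image (one patch
per source, so annotated sets carry no within-image leakage). A single draw
can still leave holes by chance, so draws are scored by FUS — the farthest
distance from any unselected data point to its nearest selected point — and
the best of `n_trials` draws is kept. Low FUS certifies that no large region
of the occupied feature space went unsampled.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `window_size` | 256 | px | patch side; 4 corner + 1 center + `n_random` windows per source |
| `n_random` | 2 | — | extra windows at uniform random positions |
| `min_skeleton_length_px` | 100 | px | patch filter: minimum skeleton arc length |
| `nu` | 10 | cells | grid cells spanning each feature's observed range |
| `r` | 4 | grid units | hypersphere radius of the sampling set |
| `k` | 100 | samples | selection size (must not exceed distinct sources) |
| `n_trials` | 1000 | — | FUS-minimization attempts |
| `t` | 0.7 | z-score units | far-apart split distance threshold |
| `alpha` | 0.9 | — | EWMA smoothing factor for loss curves |
| `eval_epoch` | 150 | epochs | loss-gap readout epoch |

Two of these deserve comment.

*The grid scale.* Taken literally, flooring z-scored features against a cell
width of `nu = 10` would collapse every feature to at most two cells, since
z-scored values rarely leave (-5, 5); no useful grid results. We therefore
interpret `nu` as the number of cells spanning each feature's observed range
(`w = (max - min) / nu` per axis), which preserves its role as the knob
trading grid sparsity against variability, and expose `cell_width` as an
explicit override for anyone wanting the literal flooring behaviour. This is
the one place where the package had to choose an interpretation; the realized
per-axis widths are stored on every `grid_dataset` so any analysis can be
replayed.

*The EWMA factor.* The loss-gap statistic delta = smoothed train loss minus
smoothed validation loss at `eval_epoch` needs a smoothing constant; alpha =
0.9 (a span of roughly 19 epochs) suppresses per-epoch variance without
erasing curve shape, and is configurable. The initialization is `s1 = x1`
with no bias correction, so constant curves are exact fixed points and
already-smoothed readouts pass through unchanged.

## The synthetic generator: what it emulates, and what it does not

`generate_vessel_image()` produces bright tubes on a dark background: smooth
random centerlines (cubic splines through uniform control points) dilated by
a disc, a vessel mean intensity modulated along the tube by a smooth random
field with configurable standard deviation, additive i.i.d. Gaussian noise,
and clipping to 0-255. Each generator parameter is the ground truth for
exactly one measured feature, which is what makes recovery tests possible:
the vessel/background mean ratio for contrast, `noise_sigma` for the wavelet
estimate, realized centerline length per area for density, and the modulation
amplitude for heterogeneity. Rasterization is binary, so noiseless images are
exactly two-valued and contrast recovers exactly.

Default parameter ranges (contrast ratio roughly 1.7-7, sigma 2-20, 2-5
curves of radius 2-4 px, heterogeneity amplitude 0-30) were chosen once to
span the qualitative regimes seen in confocal vasculature — faint noisy
acquisitions through bright dense ones — and are not tuned further.

The generator does *not* emulate a point-spread function, depth attenuation,
illumination gradients, autofluorescent background texture, or correlated
noise. Passing recovery tests therefore demonstrates that the feature
extractors measure what they claim on images whose ground truth is known; it
does not certify accuracy on real confocal data, where mask quality and
optical effects add error sources the generator omits.

## Numerical choices and degenerate inputs

- Standard deviations are population (divide by N) throughout.
- Gaussian blur uses symmetric reflect padding, so patch borders do not
  darken; kernel radius is `ceiling(4 * sigma)`.
- Skeletonization is iterative two-subiteration parallel thinning
  (Zhang-Suen), vectorized over the foreground bounding box. It preserves
  8-connectivity on tubular shapes, is idempotent on one-pixel lines, and
  always returns a subset of the foreground. Like all thinning schemes in
  this family it can erase degenerate blobs smaller than its templates (an
  isolated 2x2 square); vessel masks produced by dilated centerlines are
  never in that regime.
- The noise estimator refuses to answer (errors) with fewer than 16
  background coefficients rather than returning an unstable value.
- clDice degenerate cases are pinned: both masks empty is 1, an empty
  skeleton on one side is 0, and a zero precision-plus-sensitivity sum is 0.
- Dice: two empty masks 1, exactly one empty 0.
- Nearest-sample ties (grid coordinates) break to the lowest sample index;
  sampling-set points are kept in lexicographic order, so seeded draws are
  reproducible across platforms.
- Trial seeds in `select_best_subset()` are `seed + 1, ..., seed + n_trials`
  and are stored with the per-trial FUS values, so any winning draw can be
  replayed exactly.
- Quartiles use linear interpolation between order statistics (R type 7);
  conventions differ enough across software that this is worth pinning.
- Feature CSVs are written with 17 significant digits so read-back reproduces
  the doubles bit-for-bit.

## Design choices where the design was open

*Patch filtering.* "Enough vessel content" is quantified as total skeleton
arc length of the window mask with a default threshold of 100 px at a 256-px
window: it is monotone in vessel content, cheap, and reuses the density
machinery. The threshold is a `patch_spec` field.

*Window coordinates.* 0-based (row, col) origins with half-open extents,
center anchored at `(floor((H - w) / 2), floor((W - w) / 2))`; random windows
are drawn with replacement (overlap is allowed by design).

*Far-apart splits.* Both sides are drawn as disjoint size-`n` sets (not
complement splits), scored by the minimum cross-set Euclidean distance on
z-scored features — the space in which the default threshold `t = 0.7` is
meaningful. The full candidate distance list is returned so a threshold can
be read off a quantile of the empirical distance distribution.

*Background margin.* The background used for contrast and noise is the exact
mask complement by default; an optional margin excludes a border zone around
vessels where partial-volume pixels could bias the background mean.

*Distances in grid coordinates.* Both the nearest-sample mapping and FUS are
computed in grid units, the space in which the sampling set lives.

## Problem sizes used in the shipped checks

The test-suite and acceptance studies run at desk scale, chosen as the
smallest sizes at which every effect is comfortably away from its decision
boundary: feature-recovery sweeps use four collections of 60 images at
128x128 (one parameter swept, others pinned mid-range; Spearman correlations
run 0.92-0.99 against a 0.9 requirement); the noise estimator is checked on
twenty 256x256 pure-noise fields at each sigma in {5, 10, 20}; selection
heterogeneity uses a 2000-point 95/5 two-cluster 4-D cloud with k = 40 and
1000 trials over 10 seeds; the end-to-end pipeline reproducibility check uses
six 160x160 sources with 64-px windows. `run_config()` defaults, by contrast,
carry the full-scale values (256-px windows, nu = 10, r = 4, k = 100, 1000
trials, t = 0.7, epoch 150).

## Known limitations

- FUS minimization is best-of-`n_trials` random search, not an optimizer; it
  removes gross coverage accidents but does not find the FUS-optimal subset.
- With `k` close to the number of distinct sources, the same-source exclusion
  makes rejection sampling slow; the draw budget (default 1e6) turns a
  pathological configuration into an error rather than a hang.
- One-dimensional feature histograms (the diagnostics report) are projections
  of a 4-D selection; flatter selected-set histograms are an indicator of
  uniform coverage, not a proof, which is why the entropy comparison is
  reported rather than asserted.
- The four features describe single-channel 2-D patches; tortuosity,
  bifurcation density and 3-D structure are out of scope.
- The package selects and evaluates; it does not train segmentation models.
  Loss-curve utilities consume per-epoch losses produced elsewhere.
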