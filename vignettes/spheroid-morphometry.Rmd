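---
title: "Spheroid morphometry in 2D and 3D: models, parameters and phantoms"
author: "spheromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spheroid morphometry in 2D and 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheromorph)
```

## The problem

Multicellular spheroids — here, multicellular aggregates of lymphoma cells
(MALC) grown one per well in round-bottom ultra-low-attachment plates — are
routinely characterized by bright-field 2D imaging: a projected silhouette
is segmented and its area converted to a *projected volume* by assuming the
object is a sphere. Light-sheet (SPIM) imaging of cleared aggregates shows
that this assumption fails: the aggregates rest on the plate with a flat
bottom, grow laterally from mid-culture on, and end up as flat oblate caps
whose top-view diameter greatly exceeds their height. The sphere-equivalent
projected volume then overestimates the real volume several-fold — by
exactly a factor 2 already for a perfect half-sphere. This package
implements both the 2D read-outs and the 3D segmentation and morphometry
needed to quantify real shape and volume, plus the propidium-iodide (PI)
cell-death read-outs used alongside them in drug testing.

## 2D morphometrics

Given a segmented projection with area $S$ (mm²) and perimeter $P$ (mm):

* projected radius $R = \sqrt{S/\pi}$ and projected volume
  $V = \tfrac{4}{3}\pi R^3$;
* circularity $\mathrm{Cir} = 4\pi S / P^2$ and sphericity index
  $\mathrm{SI} = \sqrt{\mathrm{Cir}}$. Both conventions circulate in the
  spheroid literature and both equal 1 for a circle; `measureShape2D()`
  reports both so either is recoverable;
* roundness $\mathrm{RI} = 4S/(\pi\,L^2)$ with $L$ the full major axis of
  the second-moment ellipse (1 for a circle, $b/a$ for an ellipse);
* solidity $S/S_{\mathrm{hull}}$, a surface-roughness indicator.

**Perimeter estimation.** Counting boundary pixels overestimates a disk's
perimeter by tens of percent and is never used. The estimator here measures
the length of the sub-pixel 0.5-level contour of the mask after Gaussian
smoothing with $\sigma = 1$ pixel (marching squares with linear
interpolation via `contourLines`). On rasterized disks of radius
$\ge 50$ px the relative error is below 1%; on a filled square the corner
rounding introduced by the smoothing biases the perimeter by under 1%, so
$\mathrm{Cir}$ stays within 0.02 of $\pi/4$. A multi-direction Crofton
estimator was considered and rejected: with the practical 4-direction
variant the perimeter of a square is underestimated by ~5%, which breaks
the $\pi/4$ check.

**Segmentation.** `segmentProjection2D()` applies a global Otsu threshold
(optionally on the inverted image for dark bright-field objects), keeps the
largest 8-connected component and fills holes, so exactly one solid object
remains. Polarity is an explicit argument, not inferred.

## The 3D segmentation pipeline

`segmentSpheroid3D()` composes, in order:

1. **Isotropic resampling** (`resampleIsotropic()`): trilinear
   interpolation onto a cubic lattice at the smallest input spacing by
   default (light-sheet stacks are typically 2 µm in z and 1.3 µm in-plane).
   Both lattices share the physical origin, with voxel centers at
   $(i - \tfrac12)\,s$.
2. **Noise estimation** (`estimateNoiseSigma()`): a 3D Laplacian high-pass
   (6× center minus the six face neighbors) has variance $42\sigma^2$ under
   i.i.d. noise; the estimator scales the median absolute residual by
   $1/(\Phi^{-1}(0.75)\sqrt{42})$. The median makes object edges — a small
   minority of voxels — irrelevant, so a noise-free piecewise-constant
   image yields ~0.
3. **Non-local means denoising** (`denoiseNLM()`): patchwise NLM with
   patch $3^3$ and search window $7^3$ (both exposed), filtering parameter
   $h = 0.8\,\hat\sigma$, and the standard noise-compensated distance
   $\max(d^2 - 2\sigma^2, 0)$ so that flat regions average maximally.
   Internally the per-offset patch distances are computed with separable
   sliding-window box filters, making the cost independent of patch size.
4. **Otsu initialization + hysteresis** (`otsuThreshold()`,
   `hysteresisSegment()`): the Otsu threshold $T$ (256-bin histogram,
   maximum between-class variance; plateau ties broken at the plateau
   midpoint) seeds a dual threshold at $0.8\,T$ and $1.2\,T$. Multiplicative
   factors keep the parametrization invariant to intensity rescaling. The
   mask keeps voxels $\ge$ low that are 26-connected to a voxel $\ge$ high.
   Gray-level histograms of cleared-aggregate stacks are bivariate
   (background + homogeneous object) or trivariate (background + bright
   peripheral rim + dim core); hysteresis bridges the dim-core regime.
5. **Cleanup**: the largest 26-connected component is kept (minimum 1000
   voxels) and internal cavities are filled by flood-filling the
   6-connected background from the border. Whether the "real volume" of a
   published aggregate included internal cavities is not stated anywhere we
   know of; filling is chosen because compact aggregates with PI-dark cores
   must not produce hollow masks, and it is documented here as a choice.

**Degenerate inputs.** A naive Otsu threshold on a pure-noise stack marks
about half the voxels, which percolate into one giant component — so an
"empty segmentation" error could never fire. The pipeline therefore
requires the Otsu class-mean separation on the denoised stack to exceed
$3\hat\sigma$ (raw noise). Any object with SNR $\ge$ 5 passes by a wide
margin; structureless stacks fail with an explicit error.

## 3D morphometrics

From the binary mask, `measureShape3D()` derives:

* **volume**: voxel count × voxel volume (mm³);
* **surface**: area of the 0.5-level iso-surface of the lightly smoothed
  mask ($\sigma = 1$ voxel), extracted by marching tetrahedra in physical
  coordinates. Exposed-voxel-face counting overestimates a sphere's surface
  by ~50% (staircase bias) and would wreck the sphericity descriptor; a
  regression test enforces that the mesh estimator is in use;
* **equivalent ellipsoid** (`equivalentEllipsoid()`): semi-axes
  $a_i = \sqrt{5\lambda_i}$ from the eigenvalues of the voxel-position
  covariance — the unique solid ellipsoid with the same second moments.
  A bounding-ellipsoid fit would be noise-brittle; the moment fit is exact
  for solid ellipsoids and rotation invariant;
* **eccentricities** $e_1 = \sqrt{1 - c^2/a^2}$,
  $e_2 = \sqrt{1 - c^2/b^2}$ (0 for a sphere, $e_1 \ge e_2$);
* **sphericity** $36\pi V^2/A^3$, kept in this printed form (it is the
  cube of the Wadell sphericity $\pi^{1/3}(6V)^{2/3}/A$; both normalize to
  1 for a sphere);
* **roundness** $6V/(\pi L^3)$ with $L = 2a$ the full moment-ellipsoid
  major axis. The form sometimes printed as $6\pi V/L^3$ evaluates to
  $\pi^2$ for a sphere and contradicts its own "1 for a perfect sphere"
  normalization; the $\pi$ belongs in the denominator and that is what is
  implemented;
* **maximum thickness and diameter** (`thicknessAndDiameter()`): the
  occupied z-extent (the plate defines the vertical axis during
  acquisition, so no re-orientation search is performed) and the maximum
  Feret diameter of the top-view projection.

## Cell-death and viability read-outs

`piDeathMetrics()` measures the PI-positive area and summed
background-subtracted PI intensity inside the bright-field mask, both
relative to the BF area. The PI threshold is Otsu's on in-mask values,
floored at background + 3 MAD of the outside-mask PI; Otsu is only trusted
when it actually separates two populations (class-mean gap
$\ge 3\,\mathrm{MAD}$), because on an all-negative or all-positive spheroid
it would split the single mode in half. Background subtraction uses the
median PI outside the mask, making the intensity ratio invariant to
constant channel offsets; whether published intensities were
background-subtracted is unstated, so subtraction is on by default and
switchable. `normalizeToControl()` divides by the untreated-control mean,
and `viabilityPercent()` implements the trypan-blue formula
$100\,L/(L+D)$.

## The phantom generator and what a green test establishes

`makePhantom3D()` rasterizes spheres, rotated ellipsoids, half-spheres and
flat-bottomed ellipsoid caps at arbitrary (possibly anisotropic) spacing,
applies a bivariate or trivariate intensity model and seeded additive
Gaussian noise. Stated-world defaults: background/core/rim gray levels
10/180/180 (bivariate) or 10/100/200 (trivariate — the core at 50% of the
rim, mimicking the denser peripheral cell layers of late aggregates), rim
thickness 15% of the smallest semi-axis, noise at SNR 6, light-sheet
spacing (2, 1.3, 1.3) µm. Ground truth (volume, surface, axes,
eccentricities, descriptors, thickness, diameter) is computed from the
continuous shape **before** rasterization — ellipsoid and cap volumes in
closed form, cap lateral surfaces by quadrature of the surface of
revolution — so recovery tests are genuine, and `rasterizeTruth()` can
re-rasterize the ideal shape on the pipeline's isotropic lattice for Dice
comparisons.

`growthSeriesSpecs()` encodes a six-day growth course with the measured
day-1/3/6 thickness–diameter pairs (265/360, 390/550, 310/1300 µm;
intermediate days interpolated): early shapes are taller-than-hemisphere
spherical caps, late shapes flat oblate caps, so the top-view diameter
grows monotonically while thickness peaks around day 3 — the regime in
which projected volume becomes misleading.

The phantoms deliberately do **not** model light-sheet optics: no stripe
artifacts, no depth-dependent attenuation, no point-spread-function
anisotropy, no uneven clearing. A green phantom suite therefore establishes
the correctness and calibration of the *algorithms* (segmentation accuracy
on known geometry, descriptor normalization, estimator bias), not
robustness to every acquisition artifact of a real microscope.

## Numerical choices and limitations

* Axis order is (z, y, x) with the plate bottom at low z; spacing is
  caller-supplied (TIFF resolution tags are unreliable across microscopes)
  with the light-sheet default (2, 1.3, 1.3) µm.
* 26-connectivity for foreground, 6-connectivity for background fills;
  8/4 in 2D.
* Otsu uses 256 bins over the observed range; histogram-plateau ties
  resolve to the plateau midpoint, which also makes the threshold of an
  idealized two-spike histogram fall mid-valley.
* NLM accumulates in single precision (relative error ~1e-5, far below the
  noise being removed) for memory-bandwidth reasons.
* Descriptors are reported unclipped; values may exceed 1 by rasterization
  noise (e.g. solidity 1.003 on a digital disk). Clipping is available at
  export (`as.data.frame(x, clip = TRUE)`).
* The equivalent-ellipsoid eccentricities are intrinsically
  noise-sensitive near the sphere ($e \propto \sqrt{\delta}$ for axis
  asymmetry $\delta$): sub-percent axis noise already produces
  $e_1 \approx 0.05$. Comparisons of eccentricities between nearly
  spherical objects should be read accordingly.
* Anisotropic stacks are upsampled along z before segmentation; the wider
  interpolated boundary ramp biases the z moment by a few tenths of a
  percent. All recovery tolerances are met including this bias.
* TIFF support is deliberately minimal (uncompressed grayscale 8/16-bit,
  either endianness on read); compressed or RGB files are rejected with
  explicit errors rather than guessed at.
* Tests and examples run phantoms at 4–5 µm spacing where only geometry
  (not resolution) matters, to keep runtimes reasonable; the defaults
  remain the acquisition values.

## A worked pipeline run

```{r pipeline, eval = FALSE}
# a day-6-like flat oblate cap, trivariate intensity, SNR 6
spec <- phantomSpec("flat_bottom_cap", axes = c(310, 650, 650),
                    capHeight = 310, spacing = c(5, 5, 5),
                    intensityModel = "trivariate", seed = 10)
ph <- makePhantom3D(spec)
mask <- segmentSpheroid3D(ph$grid)
m3 <- measureShape3D(mask)

proj <- segmentProjection2D(maxProjection(ph$grid), "bright_object")
m2 <- measureShape2D(proj)

c(real = m3@volume, projected = m2@volume,
  ratio = m2@volume / m3@volume, sphericity = m3@sphericity)
#>       real  projected      ratio sphericity
#>      0.274      1.150      4.194      0.281
```

The projected volume (1.15 mm³) overestimates the real volume
(0.27 mm³) more than four-fold, while the 2D sphericity index of the same
projection is near 1 — the quantitative core of why flat-bottomed
aggregates require 3D imaging.
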