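#' @import methods
NULL

# ---------------------------------------------------------------------------
# Image containers
# ---------------------------------------------------------------------------

#' VoxelGrid: a 3D scalar image with physical voxel spacing
#'
#' The central container for raw and denoised image stacks. The array is
#' indexed `[z, y, x]`: axis 1 (`z`) is the optical/gravitational axis, with
#' the plate bottom at low `z`. `spacing` gives the physical voxel size in
#' micrometers per voxel as `(sz, sy, sx)`.
#'
#' @slot data 3D numeric array of non-negative, finite intensities
#'   (arbitrary units), dim = `(nz, ny, nx)`.
#' @slot spacing numeric(3), micrometers per voxel along `(z, y, x)`;
#'   all components strictly positive.
#' @slot channel free-text channel label (e.g. `"BF"`, `"PI"`, `"Ki67"`).
#'
#' @seealso [readStack()], [maxProjection()], [segmentSpheroid3D()]
#' @export
setClass("VoxelGrid",
  representation(data = "array", spacing = "numeric", channel = "character"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(2.0, 1.3, 1.3),
            channel = ""))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must have exactly 3 axes (z, y, x)")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (sz, sy, sx)")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Image2D: a 2D image with physical pixel size
#'
#' @slot data numeric matrix, indexed `[y, x]`.
#' @slot pixelSize numeric(2), micrometers per pixel `(py, px)`, positive.
#' @slot channel free-text channel label.
#' @export
setClass("Image2D",
  representation(data = "matrix", pixelSize = "numeric",
                 channel = "character"),
  prototype(data = matrix(0, 1, 1), pixelSize = c(1.3, 1.3), channel = ""))

setValidity("Image2D", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 2L)
    msg <- c(msg, "data must be a 2D matrix")
  if (length(object@pixelSize) != 2L || any(!is.finite(object@pixelSize)) ||
      any(object@pixelSize <= 0))
    msg <- c(msg, "pixelSize must be 2 positive values (py, px)")
  if (length(msg)) msg else TRUE
})

#' Mask3D: a binary 3D segmentation mask
#'
#' Shares the geometry conventions of [VoxelGrid-class].
#'
#' @slot data logical 3D array.
#' @slot spacing numeric(3), micrometers per voxel `(sz, sy, sx)`.
#' @export
setClass("Mask3D",
  representation(data = "array", spacing = "numeric"),
  prototype(data = array(FALSE, c(1, 1, 1)), spacing = c(1.3, 1.3, 1.3)))

setValidity("Mask3D", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L || !is.logical(object@data))
    msg <- c(msg, "data must be a logical 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' Mask2D: a binary 2D segmentation mask
#'
#' @slot data logical matrix, indexed `[y, x]`.
#' @slot pixelSize numeric(2), micrometers per pixel `(py, px)`.
#' @export
setClass("Mask2D",
  representation(data = "matrix", pixelSize = "numeric"),
  prototype(data = matrix(FALSE, 1, 1), pixelSize = c(1.3, 1.3)))

setValidity("Mask2D", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 2L || !is.logical(object@data))
    msg <- c(msg, "data must be a logical matrix")
  if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
    msg <- c(msg, "pixelSize must be 2 positive values")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Parameters and results
# ---------------------------------------------------------------------------

#' SegmentationParams: tuning knobs of the 3D segmentation pipeline
#'
#' Hysteresis thresholds are initialized around the Otsu threshold `T` as
#' `low = lowFactor * T` and `high = highFactor * T`; multiplicative factors
#' keep the parametrization invariant to intensity rescaling.
#'
#' @slot lowFactor low hysteresis threshold as a multiple of the Otsu
#'   threshold; in `(0, 1]`. Default 0.8.
#' @slot highFactor high hysteresis threshold as a multiple of the Otsu
#'   threshold; `>= 1`. Default 1.2.
#' @slot denoiseStrength non-local means filtering parameter `h` as a
#'   multiple of the estimated noise sigma; `>= 0` (0 disables denoising).
#'   Default 0.8.
#' @slot targetSpacing isotropic resampling pitch in micrometers; `NA` means
#'   the smallest input spacing.
#' @slot minComponentVoxels minimum voxel count of the retained component.
#'   Default 1000.
#' @slot patchRadius non-local means patch radius in voxels (patch edge
#'   `2r+1`). Default 1 (3^3 patches).
#' @slot searchRadius non-local means search window radius in voxels.
#'   Default 3 (7^3 window).
#' @export
setClass("SegmentationParams",
  representation(lowFactor = "numeric", highFactor = "numeric",
                 denoiseStrength = "numeric", targetSpacing = "numeric",
                 minComponentVoxels = "numeric", patchRadius = "integer",
                 searchRadius = "integer"),
  prototype(lowFactor = 0.8, highFactor = 1.2, denoiseStrength = 0.8,
            targetSpacing = NA_real_, minComponentVoxels = 1000,
            patchRadius = 1L, searchRadius = 3L))

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (!(object@lowFactor > 0 && object@lowFactor <= 1))
    msg <- c(msg, "lowFactor must be in (0, 1]")
  if (object@highFactor < 1)
    msg <- c(msg, "highFactor must be >= 1")
  if (object@denoiseStrength < 0)
    msg <- c(msg, "denoiseStrength must be >= 0")
  if (!is.na(object@targetSpacing) && object@targetSpacing <= 0)
    msg <- c(msg, "targetSpacing must be positive")
  if (object@patchRadius < 0L || object@searchRadius < 1L)
    msg <- c(msg, "patchRadius must be >= 0 and searchRadius >= 1")
  if (length(msg)) msg else TRUE
})

#' EllipsoidAxes: semi-axes of the equivalent ellipsoid
#'
#' @slot a longest semi-axis, micrometers.
#' @slot b second semi-axis, micrometers.
#' @slot c shortest semi-axis, micrometers.
#' @export
setClass("EllipsoidAxes",
  representation(a = "numeric", b = "numeric", c = "numeric"),
  prototype(a = 1, b = 1, c = 1))

setValidity("EllipsoidAxes", function(object) {
  if (!(object@a >= object@b && object@b >= object@c && object@c > 0))
    "semi-axes must satisfy a >= b >= c > 0" else TRUE
})

#' Morphometrics2D: 2D projection shape descriptors
#'
#' All areas are mm^2, lengths mm, volumes mm^3. `circularity` is
#' 4*pi*S/P^2; `sphericityIndex` its square root (both are reported because
#' the two conventions coexist in the spheroid literature; each equals 1 for
#' a perfect circle). `roundness` is 4*S/(pi*majorAxis^2) with the major
#' axis from the second-moment ellipse; `solidity` is S over the convex hull
#' area. `radius` and `volume` are the sphere-equivalent projected radius
#' R = sqrt(S/pi) and projected volume V = (4/3)*pi*R^3. Raw (unclipped)
#' index values are stored.
#'
#' @slot area mm^2
#' @slot perimeter mm
#' @slot circularity dimensionless
#' @slot sphericityIndex dimensionless
#' @slot roundness dimensionless
#' @slot solidity dimensionless
#' @slot radius mm
#' @slot volume mm^3
#' @export
setClass("Morphometrics2D",
  representation(area = "numeric", perimeter = "numeric",
                 circularity = "numeric", sphericityIndex = "numeric",
                 roundness = "numeric", solidity = "numeric",
                 radius = "numeric", volume = "numeric"))

#' Morphometrics3D: 3D shape descriptors of a segmented spheroid
#'
#' @slot volume real volume, mm^3 (voxel count x voxel volume, cavities
#'   filled).
#' @slot surface iso-surface mesh area, mm^2.
#' @slot axes [EllipsoidAxes-class] of the moment-equivalent ellipsoid,
#'   micrometers.
#' @slot e1,e2 eccentricities `sqrt(1 - c^2/a^2)` and `sqrt(1 - c^2/b^2)`;
#'   0 for a sphere.
#' @slot sphericity `36*pi*V^2/A^3`; 1 for a sphere.
#' @slot roundness `6*V/(pi*L^3)` with `L = 2a` the full major axis; 1 for
#'   a sphere.
#' @slot maxThickness vertical (z) extent, micrometers.
#' @slot maxDiameter maximum Feret diameter of the top-view projection,
#'   micrometers.
#' @export
setClass("Morphometrics3D",
  representation(volume = "numeric", surface = "numeric",
                 axes = "EllipsoidAxes", e1 = "numeric", e2 = "numeric",
                 sphericity = "numeric", roundness = "numeric",
                 maxThickness = "numeric", maxDiameter = "numeric"))

#' DeathMetrics: propidium-iodide cell-death read-outs
#'
#' @slot bfArea bright-field (whole spheroid) projected area, mm^2.
#' @slot piArea PI-positive area inside the BF mask, mm^2.
#' @slot piIntensity summed background-subtracted PI intensity inside the BF
#'   mask, arbitrary units.
#' @slot piAreaRatio piArea / bfArea.
#' @slot piIntensityRatio piIntensity / bfArea, a.u. per mm^2.
#' @slot piThreshold the PI threshold actually applied, a.u.
#' @slot background the background PI level subtracted, a.u.
#' @export
setClass("DeathMetrics",
  representation(bfArea = "numeric", piArea = "numeric",
                 piIntensity = "numeric", piAreaRatio = "numeric",
                 piIntensityRatio = "numeric", piThreshold = "numeric",
                 background = "numeric"))

#' GroundTruth: analytic truth attached to a synthetic phantom
#'
#' All scalar fields are derived in closed form from the continuous shape
#' before rasterization, so recovery tests against them are genuine. For
#' half-shapes (half-sphere, flat-bottomed caps) `axes`, `e1`, `e2` refer to
#' the generating ellipsoid, not the moment-fit of the truncated solid, and
#' `sphericity`/`roundness` are computed from the analytic volume/surface of
#' the truncated solid.
#'
#' @slot mask [Mask3D-class] rasterization of the ideal (noise-free) shape.
#' @slot volume mm^3.
#' @slot surface mm^2 (closed form, or 1D quadrature of the surface of
#'   revolution for caps).
#' @slot axes generating semi-axes, micrometers ([EllipsoidAxes-class]).
#' @slot e1,e2 analytic eccentricities of the generating ellipsoid.
#' @slot sphericity,roundness analytic descriptor values.
#' @slot thickness,diameter micrometers.
#' @slot center physical center used at rasterization, micrometers (z, y, x).
#' @slot rotation 3x3 rotation matrix applied to the shape.
#' @slot shape shape name.
#' @slot capBase for cap shapes, the cut height z0 relative to the ellipsoid
#'   center, micrometers (`NA` otherwise).
#' @slot axesLocal generating semi-axes in grid order (z, y, x),
#'   micrometers, before rotation; used by [rasterizeTruth()].
#' @export
setClass("GroundTruth",
  representation(mask = "Mask3D", volume = "numeric", surface = "numeric",
                 axes = "EllipsoidAxes", e1 = "numeric", e2 = "numeric",
                 sphericity = "numeric", roundness = "numeric",
                 thickness = "numeric", diameter = "numeric",
                 center = "numeric", rotation = "matrix",
                 shape = "character", capBase = "numeric",
                 axesLocal = "numeric"))
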