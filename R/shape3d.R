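# 3D shape descriptors computed from a binary mask: moment-equivalent
# ellipsoid, eccentricities, sphericity, roundness, mesh surface area,
# maximum thickness (z extent) and top-view maximum diameter.

#' Moment-equivalent ellipsoid of a 3D mask
#'
#' Semi-axes of the uniform solid ellipsoid sharing the mask's second
#' central moments: `a_i = sqrt(5 * lambda_i)` where `lambda_i` are the
#' eigenvalues of the voxel-position covariance in physical units, sorted
#' descending. Exact for solid ellipsoids (up to rasterization), and
#' invariant under rotation of the shape.
#'
#' @param mask a non-empty [Mask3D-class] with at least 4 non-coplanar
#'   voxels
#' @return an [EllipsoidAxes-class] (micrometers)
#' @export
equivalentEllipsoid <- function(mask) {
  stopifnot(is(mask, "Mask3D"))
  idx <- which(mask@data, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  co <- sweep(idx - 0.5, 2, mask@spacing, "*")
  cc <- sweep(co, 2, colMeans(co))
  cv <- crossprod(cc) / nrow(cc)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (ev[3] <= 0)
    stop("mask has fewer than 4 non-coplanar voxels")
  ax <- sqrt(5 * ev)
  new("EllipsoidAxes", a = ax[1], b = ax[2], c = ax[3])
}

#' Ellipsoid eccentricities
#'
#' `e1 = sqrt(1 - c^2/a^2)`, `e2 = sqrt(1 - c^2/b^2)` for semi-axes
#' `a >= b >= c > 0`. Both are 0 for a perfect sphere and approach 1 with
#' increasing flattening; `e1 >= e2` always.
#'
#' @param axes an [EllipsoidAxes-class], or numeric(3) `(a, b, c)` with
#'   `a >= b >= c > 0`
#' @return named numeric `c(e1 =, e2 =)`
#' @export
eccentricities <- function(axes) {
  if (is(axes, "EllipsoidAxes")) axes <- semiAxes(axes)
  a <- axes[[1]]; b <- axes[[2]]; cc <- axes[[3]]
  if (!(cc > 0)) stop("semi-axes must be positive")
  if (!(a >= b && b >= cc)) stop("semi-axes must satisfy a >= b >= c")
  c(e1 = sqrt(1 - cc^2 / a^2), e2 = sqrt(1 - cc^2 / b^2))
}

#' 3D sphericity descriptor
#'
#' `36 * pi * volume^2 / surface^3`: 1 for a perfect sphere, decreasing
#' with surface rugosity or deformation. (This is the cube of the Wadell
#' sphericity `pi^(1/3) * (6V)^(2/3) / A`; both conventions normalize to 1
#' for a sphere.) Dimensionless and scale invariant when volume and surface
#' use consistent units (mm^3 and mm^2).
#'
#' @param volume volume, mm^3 (positive)
#' @param surface surface area, mm^2 (positive)
#' @return sphericity, dimensionless
#' @export
sphericity3D <- function(volume, surface) {
  if (any(volume <= 0) || any(surface <= 0))
    stop("volume and surface must be positive")
  36 * pi * volume^2 / surface^3
}

#' 3D roundness descriptor
#'
#' `6 * volume / (pi * majorAxis^3)` with `majorAxis` the full length of the
#' longest axis (`2a`): the ratio of the volume to that of the sphere whose
#' diameter is the major axis. Equals 1 for a perfect sphere and decreases
#' with deformation.
#'
#' @param volume volume, mm^3 (positive)
#' @param majorAxis full major axis length, mm (positive)
#' @return roundness, dimensionless
#' @export
roundness3D <- function(volume, majorAxis) {
  if (any(volume <= 0) || any(majorAxis <= 0))
    stop("volume and majorAxis must be positive")
  6 * volume / (pi * majorAxis^3)
}

#' Mesh surface area of a 3D mask
#'
#' Area of the 0.5-level iso-surface of the lightly Gaussian-smoothed mask,
#' extracted by marching tetrahedra in physical coordinates. Counting
#' exposed voxel faces instead would overestimate a sphere's area by ~50%
#' (staircase bias) and is not used.
#'
#' @param mask a non-empty [Mask3D-class]
#' @param smoothSigma Gaussian pre-smoothing in voxels (default 1)
#' @return surface area, mm^2
#' @export
surfaceArea <- function(mask, smoothSigma = 1) {
  stopifnot(is(mask, "Mask3D"))
  if (!any(mask@data)) stop("empty mask")
  d <- dim(mask@data)
  pad <- 3L
  f <- array(0, d + 2L * pad)
  f[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask@data)
  fs <- cpp_gauss3(as.numeric(f), dim(f), rep(smoothSigma, 3))
  cpp_surface_area_mt(fs, dim(f), mask@spacing, 0.5) / 1e6
}

#' Maximum thickness and top-view maximum diameter
#'
#' Thickness is the vertical extent along the grid z axis (the flat plate
#' bottom defines z during acquisition, so no re-orientation search is
#' performed): `(max occupied z - min occupied z + 1) * sz`. The diameter is
#' the maximum Feret diameter of the top-view (xy) projection, both in
#' micrometers.
#'
#' @param mask a non-empty [Mask3D-class]
#' @return named numeric `c(maxThickness =, maxDiameter =)`, micrometers
#' @export
thicknessAndDiameter <- function(mask) {
  stopifnot(is(mask, "Mask3D"))
  m <- mask@data
  if (!any(m)) stop("empty mask")
  zocc <- which(rowSums(m, dims = 1) > 0)
  thickness <- (max(zocc) - min(zocc) + 1) * mask@spacing[1]

  proj <- colSums(m, dims = 1) > 0  # (ny, nx)
  idx <- which(proj, arr.ind = TRUE)
  yc <- (idx[, 1] - 0.5) * mask@spacing[2]
  xc <- (idx[, 2] - 0.5) * mask@spacing[3]
  hull <- grDevices::chull(xc, yc)
  hx <- xc[hull]; hy <- yc[hull]
  dmax <- if (length(hull) == 1L) 0 else
    max(stats::dist(cbind(hx, hy)))
  c(maxThickness = thickness, maxDiameter = dmax)
}

#' All 3D morphometrics of a segmented spheroid
#'
#' Volume is the foreground voxel count times the voxel volume (cavities
#' are filled upstream by [segmentSpheroid3D()]); all remaining descriptors
#' come from [surfaceArea()], [equivalentEllipsoid()], [eccentricities()],
#' [sphericity3D()], [roundness3D()] and [thicknessAndDiameter()]. The
#' major axis entering roundness is the full moment-ellipsoid axis `2a`.
#'
#' @param mask a non-empty [Mask3D-class], typically from
#'   [segmentSpheroid3D()]
#' @return a [Morphometrics3D-class]
#' @export
measureShape3D <- function(mask) {
  stopifnot(is(mask, "Mask3D"))
  n <- sum(mask@data)
  if (n == 0) stop("empty mask")
  volume <- n * prod(mask@spacing) / 1e9       # um^3 -> mm^3
  surface <- surfaceArea(mask)
  axes <- equivalentEllipsoid(mask)
  ecc <- eccentricities(axes)
  td <- thicknessAndDiameter(mask)
  new("Morphometrics3D",
      volume = volume, surface = surface, axes = axes,
      e1 = unname(ecc["e1"]), e2 = unname(ecc["e2"]),
      sphericity = sphericity3D(volume, surface),
      roundness = roundness3D(volume, 2 * axes@a / 1e3),
      maxThickness = unname(td["maxThickness"]),
      maxDiameter = unname(td["maxDiameter"]))
}
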