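# The 3D segmentation pipeline: isotropic resampling, noise-adaptive
# non-local means denoising, Otsu-initialized hysteresis thresholding,
# connected-component and cavity cleanup.

#' Resample a stack onto an isotropic lattice
#'
#' Trilinear interpolation; both lattices share the physical origin (voxel
#' centers at `(i - 0.5) * spacing`) so the physical extent is preserved to
#' within one voxel per axis. A grid already at the target spacing is
#' returned unchanged.
#'
#' @param grid a [VoxelGrid-class]
#' @param targetSpacing isotropic voxel pitch in micrometers; default the
#'   smallest input spacing (upsampling the coarse axis, typically z)
#' @return a [VoxelGrid-class] with spacing `(t, t, t)`
#' @export
resampleIsotropic <- function(grid, targetSpacing = NULL) {
  stopifnot(is(grid, "VoxelGrid"))
  t <- if (is.null(targetSpacing)) min(grid@spacing) else targetSpacing
  if (!is.finite(t) || t <= 0) stop("targetSpacing must be positive")
  if (all(grid@spacing == t)) return(grid)
  sdim <- dim(grid@data)
  odim <- pmax(1L, as.integer(round(sdim * grid@spacing / t)))
  out <- cpp_resample_trilinear(as.numeric(grid@data), sdim, grid@spacing,
                                odim, rep(t, 3))
  VoxelGrid(array(out, odim), spacing = rep(t, 3), channel = grid@channel)
}

#' Robust estimate of the additive noise standard deviation
#'
#' High-pass pseudo-residuals from a 3D Laplacian kernel (6 x center minus
#' the six face neighbors), scaled by the median absolute value so that pure
#' Gaussian noise of standard deviation sigma yields sigma. The median makes
#' the estimate insensitive to object edges, which populate only the tail of
#' the residual distribution.
#'
#' @param grid a [VoxelGrid-class], at least 8 voxels along every axis
#' @return estimated noise sigma (intensity units), always `>= 0`
#' @export
estimateNoiseSigma <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  a <- grid@data
  d <- dim(a)
  if (any(d < 8L)) stop("grid must be at least 8x8x8 voxels")
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  r <- 6 * a[i, j, k] -
    a[i - 1, j, k] - a[i + 1, j, k] -
    a[i, j - 1, k] - a[i, j + 1, k] -
    a[i, j, k - 1] - a[i, j, k + 1]
  # Var(r) = 42 sigma^2 for iid noise; median|N(0,s)| = qnorm(0.75) * s
  stats::median(abs(r)) / (stats::qnorm(0.75) * sqrt(42))
}

#' Non-local means denoising of a 3D stack
#'
#' Patch-based non-local averaging with filtering parameter
#' `h = strength * sigma`. Patch distances are corrected for the noise
#' contribution (`max(d^2 - 2*sigma^2, 0)`), so in flat regions weights
#' approach 1 and the filter averages the whole search window, while across
#' structure boundaries weights vanish. `strength = 0` returns the input
#' unchanged.
#'
#' @param grid a [VoxelGrid-class]
#' @param sigma noise standard deviation; default [estimateNoiseSigma()]
#' @param strength `h` as a multiple of `sigma` (default 0.8)
#' @param patchRadius patch radius in voxels (default 1: 3^3 patches)
#' @param searchRadius search window radius in voxels (default 3: 7^3)
#' @return a denoised [VoxelGrid-class] with unchanged geometry
#' @export
denoiseNLM <- function(grid, sigma = NULL, strength = 0.8,
                       patchRadius = 1L, searchRadius = 3L) {
  stopifnot(is(grid, "VoxelGrid"))
  if (strength < 0) stop("strength must be >= 0")
  if (is.null(sigma)) sigma <- estimateNoiseSigma(grid)
  if (sigma < 0) stop("sigma must be >= 0")
  if (strength == 0 || sigma == 0) return(grid)
  out <- cpp_nlm3d(as.numeric(grid@data), dim(grid@data), sigma,
                   strength * sigma, as.integer(patchRadius),
                   as.integer(searchRadius))
  VoxelGrid(array(out, dim(grid@data)), spacing = grid@spacing,
            channel = grid@channel)
}

#' Hysteresis (dual) thresholding
#'
#' The mask contains all voxels `>= low` that are 26-connected to at least
#' one voxel `>= high`. With `low == high` this reduces to single
#' thresholding.
#'
#' @param grid a [VoxelGrid-class]
#' @param low,high thresholds in intensity units, `low <= high`
#' @return a [Mask3D-class]
#' @export
hysteresisSegment <- function(grid, low, high) {
  stopifnot(is(grid, "VoxelGrid"))
  if (low > high) stop("low threshold must not exceed high threshold")
  m <- cpp_hysteresis(as.numeric(grid@data), dim(grid@data), low, high)
  Mask3D(array(m, dim(grid@data)), spacing = grid@spacing)
}

#' Segment a spheroid in a 3D stack
#'
#' The full pipeline: isotropic resampling, noise sigma estimation,
#' non-local means denoising, Otsu threshold `T`, hysteresis thresholding at
#' `(lowFactor * T, highFactor * T)`, retention of the largest 26-connected
#' component, and filling of internal cavities (compact spheroids with
#' dim cores must not produce hollow masks). The output mask carries the
#' isotropic spacing.
#'
#' A contrast guard rejects structureless inputs: if the separation of the
#' two Otsu class means on the denoised grid is below three times the raw
#' noise sigma, no real foreground exists (a naive threshold on pure noise
#' would otherwise mark about half the voxels) and an empty-segmentation
#' error is raised.
#'
#' @param grid a [VoxelGrid-class], non-constant
#' @param params a [SegmentationParams-class]
#' @return a [Mask3D-class]; attributes `otsu`, `noiseSigma` record the
#'   threshold and noise estimate used
#' @export
segmentSpheroid3D <- function(grid, params = SegmentationParams()) {
  stopifnot(is(grid, "VoxelGrid"), is(params, "SegmentationParams"))
  if (diff(range(grid@data)) == 0) stop("constant grid: cannot segment")
  t <- if (is.na(params@targetSpacing)) min(grid@spacing) else
    params@targetSpacing
  g <- resampleIsotropic(grid, t)
  sig <- estimateNoiseSigma(g)
  g <- denoiseNLM(g, sigma = sig, strength = params@denoiseStrength,
                  patchRadius = params@patchRadius,
                  searchRadius = params@searchRadius)
  thr <- otsuThreshold(g)
  v <- g@data
  mu0 <- mean(v[v < thr]); mu1 <- mean(v[v >= thr])
  if (!is.finite(mu0) || !is.finite(mu1) || (mu1 - mu0) < 3 * sig)
    stop("empty segmentation: no foreground contrast above the noise level")
  m <- cpp_hysteresis(as.numeric(v), dim(v), params@lowFactor * thr,
                      params@highFactor * thr)
  if (!any(m)) stop("empty segmentation: all voxels below threshold")
  m <- cpp_largest_component(m, dim(v))
  if (sum(m) < params@minComponentVoxels)
    stop("largest component has ", sum(m), " voxels, below the minimum of ",
         params@minComponentVoxels)
  m <- cpp_fill_holes(m, dim(v))
  out <- Mask3D(array(m, dim(v)), spacing = rep(t, 3))
  attr(out, "otsu") <- thr
  attr(out, "noiseSigma") <- sig
  out
}
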