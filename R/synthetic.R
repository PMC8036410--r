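# Seeded synthetic phantoms with analytic ground truth. Every pipeline
# stage and every acceptance property runs against these; no external image
# data is required anywhere in the package.
#
# The phantoms emulate the gray-level structure of cleared-spheroid
# light-sheet stacks: a dark background plus either a homogeneous object
# (bivariate histogram) or a bright peripheral rim around a dimmer core
# (trivariate histogram, mirroring the higher peripheral cell density of
# late-stage aggregates), with additive Gaussian noise and optionally
# anisotropic voxel spacing. Geometry is flat-bottomed where the real
# samples are: aggregates rest on the plate, so half-spheres and
# flat-bottomed caps are first-class shapes.

#' PhantomSpec: a fully stated synthetic phantom
#'
#' @slot shape one of `"sphere"`, `"ellipsoid"`, `"half_sphere"`,
#'   `"flat_bottom_cap"`.
#' @slot axes numeric(3) generating semi-axes in micrometers, in grid order
#'   `(z, y, x)` (vertical first). For a sphere all three equal the radius;
#'   for caps the lateral axes must be equal.
#' @slot spacing numeric(3) voxel spacing, micrometers `(sz, sy, sx)`.
#' @slot intensityModel `"bivariate"` (background + homogeneous object) or
#'   `"trivariate"` (background + bright rim + dim core).
#' @slot levels named numeric: `background`, `core`, `rim` gray levels
#'   (arbitrary units). Bivariate phantoms use the `core` level for the
#'   whole object.
#' @slot rimFraction rim thickness as a fraction of the smallest semi-axis,
#'   in `[0, 1)` (trivariate only; default 0.15).
#' @slot noiseSigma additive Gaussian noise standard deviation; the default
#'   is `(core - background) / 6`, i.e. SNR 6.
#' @slot seed integer RNG seed; the same spec and seed give a bit-identical
#'   stack.
#' @slot capHeight cap thickness from the flat bottom to the top,
#'   micrometers (cap shapes only).
#' @slot rotation 3x3 rotation matrix applied to the shape (full shapes
#'   only; caps keep their flat bottom horizontal).
#' @slot pad background margin around the shape, in voxels.
#' @export
setClass("PhantomSpec",
  representation(shape = "character", axes = "numeric", spacing = "numeric",
                 intensityModel = "character", levels = "numeric",
                 rimFraction = "numeric", noiseSigma = "numeric",
                 seed = "integer", capHeight = "numeric",
                 rotation = "matrix", pad = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!object@shape %in% c("sphere", "ellipsoid", "half_sphere",
                           "flat_bottom_cap"))
    msg <- c(msg, "unknown shape")
  if (length(object@axes) != 3L || any(object@axes <= 0))
    msg <- c(msg, "axes must be 3 positive semi-axes (z, y, x)")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  if (!object@intensityModel %in% c("bivariate", "trivariate"))
    msg <- c(msg, "intensityModel must be bivariate or trivariate")
  if (!all(c("background", "core", "rim") %in% names(object@levels)))
    msg <- c(msg, "levels must name background, core and rim")
  if (object@rimFraction < 0 || object@rimFraction >= 1)
    msg <- c(msg, "rimFraction must be in [0, 1)")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@shape %in% c("half_sphere", "flat_bottom_cap")) {
    if (is.na(object@capHeight) || object@capHeight <= 0 ||
        object@capHeight > 2 * object@axes[1])
      msg <- c(msg, "capHeight must be in (0, 2 * vertical semi-axis]")
    if (abs(object@axes[2] - object@axes[3]) > 1e-9)
      msg <- c(msg, "cap shapes require equal lateral semi-axes")
  }
  if (!identical(dim(object@rotation), c(3L, 3L)))
    msg <- c(msg, "rotation must be a 3x3 matrix")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param shape `"sphere"`, `"ellipsoid"`, `"half_sphere"` or
#'   `"flat_bottom_cap"`
#' @param axes for `"sphere"` and `"half_sphere"` a single radius
#'   (micrometers); otherwise the three semi-axes `(z, y, x)` in micrometers
#' @param spacing voxel spacing `(sz, sy, sx)`, micrometers; default
#'   `c(2.0, 1.3, 1.3)` (the light-sheet acquisition geometry)
#' @param intensityModel `"bivariate"` or `"trivariate"`
#' @param levels named gray levels `c(background =, core =, rim =)`;
#'   defaults 10 / 180 / 180 (bivariate) or 10 / 100 / 200 (trivariate:
#'   core at 50% of the rim)
#' @param rimFraction rim thickness as a fraction of the smallest semi-axis
#'   (default 0.15)
#' @param noiseSigma noise standard deviation; default
#'   `(core - background)/6` (SNR 6)
#' @param seed integer RNG seed (mandatory)
#' @param capHeight cap thickness, micrometers; default for
#'   `"half_sphere"` the vertical semi-axis (flat cut through the center)
#' @param rotation 3x3 rotation matrix (full shapes only)
#' @param pad background margin in voxels (default 4)
#' @return a [PhantomSpec-class]
#' @seealso [makePhantom3D()]
#' @export
phantomSpec <- function(shape, axes, spacing = c(2.0, 1.3, 1.3),
                        intensityModel = c("bivariate", "trivariate"),
                        levels = NULL, rimFraction = 0.15,
                        noiseSigma = NULL, seed,
                        capHeight = NULL, rotation = diag(3), pad = 4) {
  intensityModel <- match.arg(intensityModel)
  if (length(axes) == 1L) axes <- rep(axes, 3)
  if (is.null(levels))
    levels <- if (intensityModel == "bivariate")
      c(background = 10, core = 180, rim = 180) else
      c(background = 10, core = 100, rim = 200)
  if (is.null(noiseSigma))
    noiseSigma <- (levels[["core"]] - levels[["background"]]) / 6
  if (is.null(capHeight))
    capHeight <- if (shape == "half_sphere") axes[1] else NA_real_
  if (shape == "half_sphere") capHeight <- axes[1]
  new("PhantomSpec", shape = shape, axes = as.numeric(axes),
      spacing = as.numeric(spacing), intensityModel = intensityModel,
      levels = levels, rimFraction = rimFraction,
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed),
      capHeight = as.numeric(capHeight), rotation = rotation,
      pad = pad)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Rasterize an (optionally rotated, optionally bottom-cut) ellipsoid.
# axes: semi-axes (z,y,x) um; rotation maps local to world (z,y,x);
# center: world coordinates um; z0: cut height relative to the center
# (keep z >= z0; NA = no cut, cut is in the world frame).
.rasterShape <- function(axes, rotation, center, z0, spacing, dims) {
  M <- rotation %*% diag(1 / axes^2) %*% t(rotation)
  out <- array(FALSE, dims)
  yr <- (seq_len(dims[2]) - 0.5) * spacing[2] - center[2]
  xr <- (seq_len(dims[3]) - 0.5) * spacing[3] - center[3]
  cross <- 2 * M[2, 3] * outer(yr, xr)
  for (i in seq_len(dims[1])) {
    z <- (i - 0.5) * spacing[1] - center[1]
    if (!is.na(z0) && z < z0) next
    A <- M[2, 2] * yr^2 + 2 * z * M[1, 2] * yr
    B <- M[3, 3] * xr^2 + 2 * z * M[1, 3] * xr
    f <- outer(A, B, "+") + cross + M[1, 1] * z^2
    out[i, , ] <- f <= 1
  }
  out
}

# Thomsen approximation to the ellipsoid surface area (max error ~1.06%).
.ellipsoidSurface <- function(a, b, c) {
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

# Lateral + base surface of an axially symmetric ellipsoid cap
# (lateral semi-axis a, vertical semi-axis c, cut at z0, kept part z>=z0).
.capSurface <- function(a, c, z0) {
  g <- function(z) 2 * pi * sqrt(a^2 * (1 - z^2 / c^2) + a^4 * z^2 / c^4)
  lateral <- stats::integrate(g, z0, c, rel.tol = 1e-9)$value
  rb2 <- a^2 * max(0, 1 - z0^2 / c^2)
  lateral + pi * rb2
}

# Volume of the same cap: pi*a^2 * integral of (1 - z^2/c^2) from z0 to c.
.capVolume <- function(a, c, z0) {
  pi * a^2 * ((c - c / 3) - (z0 - z0^3 / (3 * c^2)))
}

#' Generate a 3D phantom stack with analytic ground truth
#'
#' Rasterizes the requested shape at the requested (possibly anisotropic)
#' spacing, applies the intensity model (trivariate: an outer shell of
#' thickness `rimFraction * min(axes)` at the rim level around a core at the
#' core level), and adds seeded Gaussian noise. Every ground-truth scalar is
#' derived from the continuous shape before rasterization (ellipsoid
#' `V = (4/3)*pi*a*b*c`, spherical/ellipsoidal caps by the cap formulas;
#' cap lateral surfaces by 1D quadrature of the surface of revolution), so
#' recovery tests against the truth are genuine.
#'
#' @param spec a [PhantomSpec-class]
#' @return `list(grid = , truth = )`: a [VoxelGrid-class] and a
#'   [GroundTruth-class]
#' @export
makePhantom3D <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  ax <- spec@axes            # (z, y, x) um
  sp <- spec@spacing
  padPhys <- spec@pad * sp
  isCap <- spec@shape %in% c("half_sphere", "flat_bottom_cap")
  z0 <- if (isCap) ax[1] - spec@capHeight else NA_real_

  rmax <- max(ax)
  if (isCap) {
    extent <- c(spec@capHeight, 2 * ax[2], 2 * ax[3]) + 2 * padPhys
    center <- c(padPhys[1] - z0, extent[2] / 2, extent[3] / 2)
    rot <- diag(3)
  } else {
    extent <- rep(2 * rmax, 3) + 2 * padPhys
    center <- extent / 2
    rot <- spec@rotation
  }
  dims <- pmax(8L, as.integer(ceiling(extent / sp)))

  ideal <- .rasterShape(ax, rot, center, z0, sp, dims)
  if (!any(ideal)) stop("shape too small for the requested grid/spacing")

  lv <- spec@levels
  img <- array(lv[["background"]], dims)
  if (spec@intensityModel == "bivariate") {
    img[ideal] <- lv[["core"]]
  } else {
    tRim <- spec@rimFraction * min(ax)
    axIn <- ax - tRim
    if (any(axIn <= 0)) stop("rimFraction leaves no core: degenerate axes")
    z0in <- if (isCap) z0 + tRim else NA_real_
    inner <- .rasterShape(axIn, rot, center, z0in, sp, dims)
    img[ideal] <- lv[["rim"]]
    img[inner] <- lv[["core"]]
  }
  if (spec@noiseSigma > 0) {
    img <- .withSeed(spec@seed, {
      img + stats::rnorm(length(img), 0, spec@noiseSigma)
    })
    img <- pmax(array(img, dims), 0)
  }

  # analytic truth
  srt <- sort(ax, decreasing = TRUE)
  if (spec@shape == "sphere") {
    r <- ax[1]
    vol <- (4 / 3) * pi * r^3
    surf <- 4 * pi * r^2
    thick <- 2 * r; diam <- 2 * r
    major <- 2 * r
  } else if (spec@shape == "ellipsoid") {
    vol <- (4 / 3) * pi * prod(ax)
    surf <- .ellipsoidSurface(srt[1], srt[2], srt[3])
    Q <- rot %*% diag(ax^2) %*% t(rot)
    thick <- 2 * sqrt(Q[1, 1])
    diam <- 2 * sqrt(max(eigen(Q[2:3, 2:3], symmetric = TRUE,
                               only.values = TRUE)$values))
    major <- 2 * srt[1]
  } else {
    a <- ax[2]; cv <- ax[1]
    vol <- .capVolume(a, cv, z0)
    surf <- .capSurface(a, cv, z0)
    thick <- spec@capHeight
    diam <- if (z0 <= 0) 2 * a else 2 * a * sqrt(1 - z0^2 / cv^2)
    major <- max(diam, thick)
  }
  ecc <- eccentricities(srt)
  truth <- new("GroundTruth",
    mask = Mask3D(ideal, spacing = sp),
    volume = vol / 1e9, surface = surf / 1e6,
    axes = new("EllipsoidAxes", a = srt[1], b = srt[2], c = srt[3]),
    e1 = unname(ecc["e1"]), e2 = unname(ecc["e2"]),
    sphericity = sphericity3D(vol / 1e9, surf / 1e6),
    roundness = roundness3D(vol / 1e9, major / 1e3),
    thickness = thick, diameter = diam,
    center = center, rotation = rot, shape = spec@shape,
    capBase = if (isCap) z0 else NA_real_, axesLocal = ax)
  list(grid = VoxelGrid(img, spacing = sp, channel = "PI"), truth = truth)
}

#' Re-rasterize the ideal phantom shape on another lattice
#'
#' Rasterizes the continuous ground-truth shape at an arbitrary spacing and
#' grid size sharing the physical origin of the phantom, e.g. the isotropic
#' lattice produced by [resampleIsotropic()]/[segmentSpheroid3D()], so that
#' voxelwise overlap (Dice) against a pipeline mask is well defined.
#'
#' @param truth a [GroundTruth-class] from [makePhantom3D()]
#' @param spacing numeric(3) target spacing, micrometers
#' @param dims integer(3) target grid size
#' @return a [Mask3D-class]
#' @export
rasterizeTruth <- function(truth, spacing, dims) {
  stopifnot(is(truth, "GroundTruth"))
  m <- .rasterShape(truth@axesLocal, truth@rotation, truth@center,
                    truth@capBase, spacing, as.integer(dims))
  Mask3D(m, spacing = spacing)
}

#' Dice overlap of two masks on the same lattice
#'
#' @param a,b [Mask3D-class] or [Mask2D-class] objects of identical
#'   dimensions
#' @return Dice coefficient in `[0, 1]`
#' @export
diceCoefficient <- function(a, b) {
  ma <- imageData(a); mb <- imageData(b)
  if (!identical(dim(ma), dim(mb))) stop("masks differ in dimensions")
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}

#' Phantom specs emulating the aggregate growth time course
#'
#' A six-day series with monotonically increasing top-view diameter and
#' non-monotone thickness: early aggregates are taller-than-hemisphere
#' spherical caps resting on the plate; from mid-series the top flattens
#' and late shapes are flat-bottomed oblate caps. Day 1/3/6 thickness and
#' diameter follow the measured growth of lymphoma aggregates seeded at
#' 2500 cells (265/360, 390/550 and 310/1300 um); intermediate days are
#' interpolated.
#'
#' @param spacing voxel spacing, micrometers; default `c(5, 5, 5)` (a
#'   decimated light-sheet geometry keeping the series affordable)
#' @param seed base RNG seed; day `d` uses `seed + d`
#' @param days subset of days 1..6 (default all)
#' @return list of [PhantomSpec-class]
#' @seealso [makeGrowthSeries()]
#' @export
growthSeriesSpecs <- function(spacing = c(5, 5, 5), seed = 1L, days = 1:6) {
  tab <- data.frame(
    day = 1:6,
    thickness = c(265, 330, 390, 380, 340, 310),
    diameter = c(360, 450, 550, 750, 1050, 1300))
  lapply(days, function(d) {
    T_ <- tab$thickness[d]; D_ <- tab$diameter[d]
    if (T_ >= D_ / 2) {
      r <- D_ / 2
      phantomSpec("flat_bottom_cap", axes = c(r, r, r), spacing = spacing,
                  capHeight = T_, seed = seed + d)
    } else {
      phantomSpec("flat_bottom_cap", axes = c(T_, D_ / 2, D_ / 2),
                  spacing = spacing, capHeight = T_, seed = seed + d)
    }
  })
}

#' Generate a phantom growth series
#'
#' @param dayParams list of [PhantomSpec-class] (at least one), e.g. from
#'   [growthSeriesSpecs()]
#' @return list of `list(grid =, truth =)` elements, as [makePhantom3D()]
#' @export
makeGrowthSeries <- function(dayParams) {
  if (!length(dayParams)) stop("at least one timepoint is required")
  lapply(dayParams, makePhantom3D)
}

#' Paired BF/PI 2D phantom for the cell-death read-out
#'
#' A bright-field image with a dark spheroid disk on a bright background,
#' and a PI image in which the requested area fraction of the disk is
#' PI-positive, either as a peripheral rim (cell death in the outer layers)
#' or as a diffuse pixelwise speckle.
#'
#' @param bfRadius spheroid radius, micrometers (default 130)
#' @param deadFraction PI-positive area fraction, in `[0, 1]`
#' @param pattern `"rim"` or `"diffuse"`
#' @param seed integer RNG seed
#' @param pixelSize micrometers per pixel `(py, px)`, default
#'   `c(1.3, 1.3)`
#' @param noiseSigma additive noise on both channels (default 5)
#' @return `list(bf = , pi = , truth = )`: two [Image2D-class] objects and
#'   a truth list with `deadFraction`, `pattern` and the ideal `bfMask`
#' @export
makePIPhantom <- function(bfRadius = 130, deadFraction,
                          pattern = c("rim", "diffuse"), seed,
                          pixelSize = c(1.3, 1.3), noiseSigma = 5) {
  pattern <- match.arg(pattern)
  if (deadFraction < 0 || deadFraction > 1)
    stop("deadFraction must be in [0, 1]")
  rpx <- bfRadius / pixelSize[2]
  n <- as.integer(2 * ceiling(rpx) + 21)
  cy <- (n / 2) * pixelSize[1]; cx <- (n / 2) * pixelSize[2]
  yc <- (seq_len(n) - 0.5) * pixelSize[1] - cy
  xc <- (seq_len(n) - 0.5) * pixelSize[2] - cx
  d2 <- outer(yc^2, xc^2, "+")
  disk <- d2 <= bfRadius^2

  .withSeed(seed, {
    bf <- matrix(200, n, n)
    bf[disk] <- 80
    bf <- bf + stats::rnorm(n * n, 0, noiseSigma)

    piimg <- matrix(10, n, n)
    if (deadFraction > 0) {
      pos <- if (pattern == "rim") {
        rin2 <- bfRadius^2 * (1 - deadFraction)
        disk & d2 >= rin2
      } else {
        disk & matrix(stats::runif(n * n) < deadFraction, n, n)
      }
      piimg[pos] <- 200
    }
    piimg <- piimg + stats::rnorm(n * n, 0, noiseSigma)

    list(bf = Image2D(pmax(bf, 0), pixelSize = pixelSize, channel = "BF"),
         pi = Image2D(pmax(piimg, 0), pixelSize = pixelSize,
                      channel = "PI"),
         truth = list(deadFraction = deadFraction, pattern = pattern,
                      bfMask = Mask2D(disk, pixelSize = pixelSize)))
  })
}
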