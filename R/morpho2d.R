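# 2D projection morphometrics: segmentation of the spheroid silhouette and
# the classical shape descriptors computed from it.
#
# Perimeter is measured as the length of the sub-pixel 0.5-level contour of
# the Gaussian-smoothed (sigma = 1 px) mask. Naive boundary-pixel counting
# overestimates disk perimeters by ~27% and is not used anywhere.

#' Otsu threshold
#'
#' Threshold maximizing the between-class variance (equivalently minimizing
#' the intraclass variance) of a 256-bin histogram over the observed data
#' range. The returned value is the bin boundary between the two classes.
#'
#' @param x numeric vector/array, [VoxelGrid-class] or [Image2D-class]
#' @param nbins number of histogram bins (default 256)
#' @return threshold, in intensity units
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  if (is(x, "VoxelGrid") || is(x, "Image2D")) x <- x@data
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite values")
  rng <- range(v)
  if (diff(rng) == 0) stop("constant input: no threshold exists")
  bw <- diff(rng) / nbins
  bin <- pmin(pmax(floor((v - rng[1]) / bw) + 1L, 1L), nbins)
  h <- tabulate(bin, nbins)
  p <- h / sum(h)
  mid <- rng[1] + (seq_len(nbins) - 0.5) * bw
  w0 <- cumsum(p)
  m0 <- cumsum(p * mid)
  mT <- m0[nbins]
  k <- seq_len(nbins - 1L)
  denom <- w0[k] * (1 - w0[k])
  bc <- ifelse(denom > 0, (mT * w0[k] - m0[k])^2 / denom, -Inf)
  # ties (an empty valley between two modes gives a flat maximum plateau)
  # are broken by the plateau midpoint
  kstar <- mean(which(bc == max(bc)))
  rng[1] + kstar * bw
}

#' Segment the spheroid in a 2D projection
#'
#' Global Otsu threshold (on the inverted image for dark objects), keep the
#' largest 8-connected foreground component, fill holes. The output always
#' contains exactly one connected component.
#'
#' @param image an [Image2D-class]; must not be constant
#' @param polarity `"dark_object"` for bright-field (spheroid darker than
#'   background) or `"bright_object"` for fluorescence
#' @return a [Mask2D-class]
#' @export
segmentProjection2D <- function(image,
                                polarity = c("dark_object",
                                             "bright_object")) {
  stopifnot(is(image, "Image2D"))
  polarity <- match.arg(polarity)
  v <- image@data
  if (diff(range(v)) == 0) stop("constant image: cannot segment")
  if (polarity == "dark_object") v <- max(v) - v
  thr <- otsuThreshold(v)
  fg <- v >= thr
  if (!any(fg)) stop("empty foreground after thresholding")
  d3 <- c(1L, dim(fg))
  m <- cpp_largest_component(as.logical(fg), d3)
  m <- cpp_fill_holes(m, d3)
  Mask2D(matrix(m, dim(fg)[1], dim(fg)[2]), pixelSize = image@pixelSize)
}

# Contour length of the 0.5 level of a lightly smoothed binary mask, in the
# physical units of pixelSize. The field is zero-padded so contours close.
.maskPerimeter <- function(mask, pixelSize, smoothSigma = 1) {
  d <- dim(mask)
  f <- matrix(0, d[1] + 4L, d[2] + 4L)
  f[3:(d[1] + 2L), 3:(d[2] + 2L)] <- as.numeric(mask)
  fs <- cpp_gauss3(as.numeric(f), c(1L, dim(f)),
                   c(0, smoothSigma, smoothSigma))
  fs <- matrix(fs, dim(f)[1], dim(f)[2])
  ycoord <- (seq_len(nrow(fs)) - 0.5) * pixelSize[1]
  xcoord <- (seq_len(ncol(fs)) - 0.5) * pixelSize[2]
  cl <- grDevices::contourLines(ycoord, xcoord, fs, levels = 0.5)
  sum(vapply(cl, function(seg) {
    sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2))
  }, numeric(1)))
}

# Shoelace area of a polygon given as two coordinate vectors.
.polyArea <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' 2D shape descriptors of a segmented projection
#'
#' Computes area `S`, perimeter, circularity `Cir = 4*pi*S/P^2`, sphericity
#' index `SI = sqrt(Cir)`, roundness `RI = 4*S/(pi*majorAxis^2)` (major axis
#' from the second-moment ellipse), solidity (S over convex-hull area),
#' sphere-equivalent projected radius `R = sqrt(S/pi)` and projected volume
#' `V = (4/3)*pi*R^3`. Both `Cir` and `SI` are reported because both
#' conventions appear in the spheroid literature (each equals 1 for a
#' circle). Raw index values are stored; clipping to 1 is applied only when
#' exporting with `as.data.frame(..., clip = TRUE)`.
#'
#' @param mask a [Mask2D-class] with exactly one connected component of at
#'   least 25 pixels
#' @return a [Morphometrics2D-class] (areas mm^2, lengths mm, volumes mm^3)
#' @seealso [segmentProjection2D()], [projectedVolume()]
#' @export
measureShape2D <- function(mask) {
  stopifnot(is(mask, "Mask2D"))
  m <- mask@data
  n <- sum(m)
  if (n == 0) stop("empty mask")
  if (n < 25) stop("mask too small (< 25 pixels)")
  d3 <- c(1L, dim(m))
  if (sum(cpp_largest_component(as.logical(m), d3)) != n)
    stop("mask has more than one connected component")

  px <- mask@pixelSize  # (py, px) um
  S_um2 <- n * px[1] * px[2]
  P_um <- .maskPerimeter(m, px)

  idx <- which(m, arr.ind = TRUE)
  yc <- (idx[, 1] - 0.5) * px[1]
  xc <- (idx[, 2] - 0.5) * px[2]
  cc <- cbind(yc - mean(yc), xc - mean(xc))
  cv <- crossprod(cc) / n
  lmax <- max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
  majorAxis <- 4 * sqrt(lmax)  # full length of the moment-ellipse major axis

  hull <- grDevices::chull(xc, yc)
  hullArea <- .polyArea(xc[hull], yc[hull])

  cir <- 4 * pi * S_um2 / P_um^2
  S_mm2 <- S_um2 / 1e6
  R_mm <- sqrt(S_mm2 / pi)
  new("Morphometrics2D",
      area = S_mm2,
      perimeter = P_um / 1e3,
      circularity = cir,
      sphericityIndex = sqrt(cir),
      roundness = 4 * S_um2 / (pi * majorAxis^2),
      solidity = S_um2 / hullArea,
      radius = R_mm,
      volume = (4 / 3) * pi * R_mm^3)
}

#' Sphere-equivalent projected volume from a projected area
#'
#' `R = sqrt(S/pi)`, `V = (4/3)*pi*R^3`. Unbiased only when the object is a
#' true sphere; for flattened spheroids it overestimates the real volume
#' (for a half-sphere by exactly a factor 2).
#'
#' @param area_mm2 projected area in mm^2 (non-negative)
#' @return projected volume in mm^3
#' @export
projectedVolume <- function(area_mm2) {
  if (any(area_mm2 < 0)) stop("area must be non-negative")
  (4 / 3) * pi * sqrt(area_mm2 / pi)^3
}
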