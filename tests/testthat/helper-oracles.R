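# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures exist anywhere in the package.

# rasterized disk mask (pixel centers), odd-ish grid with margin
rasterDisk <- function(r, n = 2 * r + 21, px = 1) {
  co <- (seq_len(n) - 0.5) - n / 2
  matrix(outer(co^2, co^2, "+") <= r^2, n, n)
}

# rasterized axis-aligned solid ellipsoid mask (z, y, x semi-axes in voxels)
rasterEllipsoid3 <- function(az, ay, ax, margin = 5) {
  nz <- 2 * ceiling(az) + 2 * margin
  ny <- 2 * ceiling(ay) + 2 * margin
  nx <- 2 * ceiling(ax) + 2 * margin
  zc <- (seq_len(nz) - 0.5) - nz / 2
  yc <- (seq_len(ny) - 0.5) - ny / 2
  xc <- (seq_len(nx) - 0.5) - nx / 2
  f <- outer((zc / az)^2, outer((yc / ay)^2, (xc / ax)^2, "+"), "+")
  array(f <= 1, c(nz, ny, nx))
}

# brute-force Otsu oracle: exhaustive intraclass-variance minimization over
# the same 256-bin histogram; ties broken by the plateau midpoint
bruteOtsu <- function(v, nbins = 256L) {
  rng <- range(v)
  bw <- diff(rng) / nbins
  bin <- pmin(pmax(floor((v - rng[1]) / bw) + 1L, 1L), nbins)
  h <- tabulate(bin, nbins)
  p <- h / sum(h)
  mid <- rng[1] + (seq_len(nbins) - 0.5) * bw
  intra <- numeric(nbins - 1L)
  for (k in seq_len(nbins - 1L)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    intra[k] <- if (w0 == 0 || w1 == 0) Inf else {
      mu0 <- sum(p[1:k] * mid[1:k]) / w0
      mu1 <- sum(p[(k + 1):nbins] * mid[(k + 1):nbins]) / w1
      sum(p[1:k] * (mid[1:k] - mu0)^2) +
        sum(p[(k + 1):nbins] * (mid[(k + 1):nbins] - mu1)^2)
    }
  }
  rng[1] + mean(which(intra == min(intra))) * bw
}

# flood-fill hysteresis oracle: iterated 26-neighborhood dilation of the
# strong seeds, constrained to voxels >= low (level-by-level BFS)
bfsHysteresis <- function(arr, low, high) {
  d <- dim(arr)
  shift <- function(m, s) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    for (ax in 1:3) {
      if (s[ax] == 1) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
      if (s[ax] == -1) { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  offsets <- expand.grid(-1:1, -1:1, -1:1)
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  weak <- arr >= low
  mask <- (arr >= high) & weak
  repeat {
    grown <- mask
    for (o in seq_len(nrow(offsets)))
      grown <- grown | shift(mask, as.numeric(offsets[o, ]))
    grown <- grown & weak
    if (identical(grown, mask)) break
    mask <- grown
  }
  mask
}

# naive exposed-voxel-face surface area (the estimator that must NOT be in
# use; kept as an oracle for the staircase-bias regression test)
naiveFaceArea <- function(arr, spacing = c(1, 1, 1)) {
  d <- dim(arr)
  shift <- function(m, s) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    for (ax in 1:3) {
      if (s[ax] == 1) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
      if (s[ax] == -1) { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  faceArea <- c(spacing[2] * spacing[3], spacing[2] * spacing[3],
                spacing[1] * spacing[3], spacing[1] * spacing[3],
                spacing[1] * spacing[2], spacing[1] * spacing[2])
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  a <- 0
  for (q in seq_along(shifts))
    a <- a + sum(arr & !shift(arr, shifts[[q]])) * faceArea[q]
  a
}

# random rotation matrix from three Euler angles
eulerRotation <- function(th) {
  Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a),
                             0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  Rz(th[1]) %*% Rx(th[2]) %*% Rz(th[3])
}
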