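test_that("Otsu threshold matches the exhaustive intraclass-variance scan", {
  # two equal spikes: threshold strictly between them, equal to brute force
  v <- c(rep(10, 500), rep(200, 500))
  t1 <- otsuThreshold(v)
  expect_gt(t1, 10); expect_lt(t1, 200)
  expect_equal(t1, bruteOtsu(v))

  # bivariate Gaussian mixture (means 30/180, sd 10): valley threshold
  set.seed(42)
  v <- c(rnorm(5000, 30, 10), rnorm(5000, 180, 10))
  t2 <- otsuThreshold(v)
  expect_gt(t2, 80); expect_lt(t2, 130)
  expect_equal(t2, bruteOtsu(v))

  expect_error(otsuThreshold(rep(3, 100)), "constant")
})

test_that("projection segmentation recovers a disk, fills holes, and needs
           contrast", {
  n <- 201
  co <- (seq_len(n) - 0.5) - n / 2
  d2 <- outer(co^2, co^2, "+")
  img <- matrix(200, n, n)
  img[d2 <= 80^2] <- 50
  set.seed(3)
  img <- img + rnorm(n * n, 0, 5)

  m <- segmentProjection2D(Image2D(img, c(1, 1)), "dark_object")
  expect_s4_class(m, "Mask2D")
  expect_lt(abs(sum(imageData(m)) / (pi * 80^2) - 1), 0.02)

  # a hole in the object is filled, so solidity is ~1
  img2 <- matrix(200, n, n)
  img2[d2 <= 80^2] <- 50
  img2[d2 <= 5^2] <- 200
  m2 <- segmentProjection2D(Image2D(img2, c(1, 1)), "dark_object")
  expect_true(all(imageData(m2)[d2 <= 5^2]))
  expect_gt(measureShape2D(m2)@solidity, 0.99)

  expect_error(segmentProjection2D(Image2D(matrix(7, 20, 20), c(1, 1))),
               "constant")
})

test_that("2D descriptors match closed forms for disk, ellipse and square", {
  # disk radius 100 px, 1 um pixels
  s <- measureShape2D(Mask2D(rasterDisk(100), pixelSize = c(1, 1)))
  expect_lt(abs(s@circularity - 1), 0.02)
  expect_lt(abs(s@sphericityIndex - 1), 0.01)
  expect_lt(abs(s@roundness - 1), 0.02)
  expect_gt(s@solidity, 0.99)
  # R = sqrt(S/pi) and V = (4/3) pi R^3 hold exactly
  expect_equal(s@radius, sqrt(s@area / pi))
  expect_equal(s@volume, (4 / 3) * pi * s@radius^3)

  # 2:1 ellipse (semi-axes 100, 50): RI = 4*pi*a*b / (pi*(2a)^2) = 0.5
  n <- 241; co <- (seq_len(n) - 0.5) - n / 2
  ell <- matrix(outer((co / 50)^2, (co / 100)^2, "+") <= 1, n, n)
  se <- measureShape2D(Mask2D(ell, pixelSize = c(1, 1)))
  expect_lt(abs(se@roundness - 0.5), 0.02)

  # filled square side 100: Cir = 4*pi*L^2/(4L)^2 = pi/4
  sq <- matrix(FALSE, 121, 121); sq[11:110, 11:110] <- TRUE
  ss <- measureShape2D(Mask2D(sq, pixelSize = c(1, 1)))
  expect_lt(abs(ss@circularity - pi / 4), 0.02)
})

test_that("dimensionless 2D indices are invariant under rescaling", {
  a <- measureShape2D(Mask2D(rasterDisk(50), pixelSize = c(1, 1)))
  b <- measureShape2D(Mask2D(rasterDisk(100), pixelSize = c(1, 1)))
  c_ <- measureShape2D(Mask2D(rasterDisk(100), pixelSize = c(2.6, 2.6)))
  for (f in c("circularity", "sphericityIndex", "roundness", "solidity")) {
    expect_lt(abs(slot(a, f) - slot(b, f)), 0.02)
    expect_equal(slot(b, f), slot(c_, f))  # pixel size cancels exactly
  }
})

test_that("measureShape2D enforces its preconditions", {
  expect_error(measureShape2D(Mask2D(matrix(FALSE, 10, 10), c(1, 1))),
               "empty")
  small <- matrix(FALSE, 10, 10); small[5, 5] <- TRUE
  expect_error(measureShape2D(Mask2D(small, c(1, 1))), "small")
  two <- matrix(FALSE, 40, 40)
  two[5:12, 5:12] <- TRUE; two[25:32, 25:32] <- TRUE
  expect_error(measureShape2D(Mask2D(two, c(1, 1))), "component")
})

test_that("projected volume follows the sphere-equivalent formula", {
  # day-6 worked example: disk of diameter 1.300 mm -> 1.15 mm^3
  expect_equal(signif(projectedVolume(pi * 0.65^2), 3), 1.15)
  # unit projected radius
  expect_equal(projectedVolume(pi), 4 * pi / 3)
  expect_identical(projectedVolume(0), 0)
  expect_error(projectedVolume(-1), "non-negative")

  # unbiased for spheres, exactly 2x for half-spheres viewed from the top
  for (r in c(0.2, 0.65, 1.7)) {
    expect_equal(projectedVolume(pi * r^2), (4 / 3) * pi * r^3)
    expect_equal(projectedVolume(pi * r^2) / ((2 / 3) * pi * r^3), 2)
  }
})
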