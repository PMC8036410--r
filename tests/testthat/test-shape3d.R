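test_that("moment-equivalent ellipsoid recovers solid-ellipsoid axes", {
  # axis-aligned (100, 80, 50) um at unit spacing: each axis within 2%
  m <- Mask3D(rasterEllipsoid3(50, 80, 100), spacing = c(1, 1, 1))
  ax <- semiAxes(equivalentEllipsoid(m))
  expect_lt(max(abs(ax / c(100, 80, 50) - 1)), 0.02)

  # sphere: a = b = c = r within 2%
  ms <- Mask3D(rasterEllipsoid3(40, 40, 40), spacing = c(1, 1, 1))
  expect_lt(max(abs(semiAxes(equivalentEllipsoid(ms)) / 40 - 1)), 0.02)

  # rotation leaves (a, b, c) unchanged within 2%
  spec <- phantomSpec("ellipsoid", axes = c(50, 80, 100),
                      spacing = c(1, 1, 1), noiseSigma = 0, seed = 1,
                      rotation = eulerRotation(c(0.7, 0.9, 0.3)))
  ph <- makePhantom3D(spec)
  axr <- semiAxes(equivalentEllipsoid(ph$truth@mask))
  expect_lt(max(abs(axr / c(100, 80, 50) - 1)), 0.02)

  expect_error(equivalentEllipsoid(
    Mask3D(array(FALSE, c(4, 4, 4)), c(1, 1, 1))), "empty")
  flat <- array(FALSE, c(4, 4, 4)); flat[2, , ] <- TRUE
  expect_error(equivalentEllipsoid(Mask3D(flat, c(1, 1, 1))),
               "non-coplanar")
})

test_that("eccentricities follow their closed form and ordering", {
  expect_equal(unname(eccentricities(c(5, 5, 5))), c(0, 0))
  e <- eccentricities(c(100, 80, 50))
  expect_equal(unname(e), c(sqrt(1 - 0.25), sqrt(1 - 2500 / 6400)))
  expect_equal(unname(e), c(0.8660254, 0.7806247), tolerance = 1e-7)

  # c -> 0 limit: both approach 1
  expect_equal(unname(eccentricities(c(100, 80, 1e-9))), c(1, 1),
               tolerance = 1e-6)

  expect_error(eccentricities(c(50, 80, 100)), "a >= b >= c")
  expect_error(eccentricities(c(1, 1, 0)), "positive")

  # e1 >= e2 for any admissible axes
  set.seed(31)
  for (i in 1:50) {
    ax <- sort(runif(3, 1, 100), decreasing = TRUE)
    e <- eccentricities(ax)
    expect_gte(e[["e1"]], e[["e2"]])
  }
})

test_that("sphericity and roundness are exactly 1 for analytic spheres and
           scale invariant", {
  for (r in c(0.1, 0.5, 2)) {
    expect_equal(sphericity3D((4 / 3) * pi * r^3, 4 * pi * r^2), 1)
    expect_equal(roundness3D((pi / 6) * (2 * r)^3, 2 * r), 1)
  }
  # 2:1:1 prolate ellipsoid, major full length L: roundness = 0.25 exactly
  L <- 2
  expect_equal(roundness3D((pi / 6) * L * (L / 2)^2, L), 0.25)
  # ellipsoid sphericity < 1 (surface from the Thomsen closed form)
  V <- (4 / 3) * pi * 2 * 1 * 1
  A <- 4 * pi * (((2 * 1)^1.6075 * 2 + (1 * 1)^1.6075) / 3)^(1 / 1.6075)
  expect_lt(sphericity3D(V, A), 1)
  # uniform scaling leaves both unchanged
  expect_equal(sphericity3D(8 * V, 4 * A), sphericity3D(V, A))
  expect_equal(roundness3D(8 * V, 2 * L), roundness3D(V, L))
  expect_error(sphericity3D(0, 1), "positive")
  expect_error(roundness3D(1, 0), "positive")
})

test_that("mesh surface area is accurate where face counting is not", {
  sph <- rasterEllipsoid3(50, 50, 50)
  m <- Mask3D(sph, spacing = c(1, 1, 1))
  A <- surfaceArea(m) * 1e6
  expect_lt(abs(A / (4 * pi * 50^2) - 1), 0.03)

  # exposed-voxel-face counting overestimates by > 30% on the same mask:
  # the regression guard that the mesh estimator is the one in use
  expect_gt(naiveFaceArea(sph) / (4 * pi * 50^2) - 1, 0.3)

  # (100, 80, 50) ellipsoid vs the Thomsen approximation
  me <- Mask3D(rasterEllipsoid3(50, 80, 100), spacing = c(1, 1, 1))
  p <- 1.6075
  thomsen <- 4 * pi * (((100 * 80)^p + (100 * 50)^p + (80 * 50)^p) /
                         3)^(1 / p)
  expect_lt(abs(surfaceArea(me) * 1e6 / thomsen - 1), 0.03)

  expect_error(surfaceArea(Mask3D(array(FALSE, c(4, 4, 4)), c(1, 1, 1))),
               "empty")
})

test_that("thickness and top-view diameter follow the mask geometry", {
  # half-sphere of radius r: thickness ~ r, diameter ~ 2r
  ph <- makePhantom3D(phantomSpec("half_sphere", axes = 60,
                                  spacing = c(1, 1, 1), noiseSigma = 0,
                                  seed = 1))
  td <- thicknessAndDiameter(ph$truth@mask)
  expect_lt(abs(td[["maxThickness"]] / 60 - 1), 0.02)
  expect_lt(abs(td[["maxDiameter"]] / 120 - 1), 0.02)

  # full sphere: thickness ~ diameter ~ 2r
  ms <- Mask3D(rasterEllipsoid3(40, 40, 40), spacing = c(1, 1, 1))
  td2 <- thicknessAndDiameter(ms)
  expect_lt(abs(td2[["maxThickness"]] / 80 - 1), 0.02)
  expect_lt(abs(td2[["maxDiameter"]] / 80 - 1), 0.02)

  # oblate (100, 100, 30) with c along z: thickness 60, diameter 200
  mo <- Mask3D(rasterEllipsoid3(30, 100, 100), spacing = c(1, 1, 1))
  td3 <- thicknessAndDiameter(mo)
  expect_lt(abs(td3[["maxThickness"]] / 60 - 1), 0.02)
  expect_lt(abs(td3[["maxDiameter"]] / 200 - 1), 0.02)

  # anisotropic spacing is honored
  mhalf <- Mask3D(imageData(ms), spacing = c(2, 1, 1))
  expect_lt(abs(thicknessAndDiameter(mhalf)[["maxThickness"]] / 160 - 1),
            0.02)
})

test_that("measureShape3D integrates the descriptors on ideal shapes", {
  # sphere r = 500 um at 5 um spacing (100 voxels radius)
  ph <- makePhantom3D(phantomSpec("sphere", axes = 500,
                                  spacing = c(5, 5, 5), noiseSigma = 0,
                                  seed = 1))
  mm <- measureShape3D(ph$truth@mask)
  expect_lt(abs(mm@volume / 0.5236 - 1), 0.02)
  expect_gte(mm@sphericity, 0.95)
  expect_gte(mm@roundness, 0.95)
  expect_lte(mm@e1, 0.15)

  # half-sphere r = 500 um: volume ~ 0.262 mm^3; its top-view disk gives a
  # projected volume of ~ 0.524 mm^3, i.e. the factor-2 overestimate
  ph2 <- makePhantom3D(phantomSpec("half_sphere", axes = 500,
                                   spacing = c(5, 5, 5), noiseSigma = 0,
                                   seed = 1))
  mm2 <- measureShape3D(ph2$truth@mask)
  expect_lt(abs(mm2@volume / 0.2618 - 1), 0.02)
  proj <- colSums(imageData(ph2$truth@mask), dims = 1) > 0
  pv <- projectedVolume(sum(proj) * 25 / 1e6)
  expect_lt(abs(pv / mm2@volume - 2), 0.05)
})

test_that("flattening a sphere monotonically degrades the 3D descriptors", {
  # 5-step oblate series (a = b = 100, c decreasing): sphericity and
  # roundness strictly decrease, e1 strictly increases
  cs <- c(100, 80, 60, 40, 25)
  sph <- rnd <- e1s <- numeric(length(cs))
  for (i in seq_along(cs)) {
    m <- Mask3D(rasterEllipsoid3(cs[i], 100, 100), spacing = c(2, 2, 2))
    mm <- measureShape3D(m)
    sph[i] <- mm@sphericity; rnd[i] <- mm@roundness; e1s[i] <- mm@e1
  }
  expect_true(all(diff(sph) < 0))
  expect_true(all(diff(rnd) < 0))
  expect_true(all(diff(e1s) > 0))
})

test_that("dimensionless 3D descriptors are scale and rotation invariant", {
  a <- measureShape3D(Mask3D(rasterEllipsoid3(25, 40, 50), c(2, 2, 2)))
  b <- measureShape3D(Mask3D(rasterEllipsoid3(50, 80, 100), c(1, 1, 1)))
  rotated <- makePhantom3D(phantomSpec("ellipsoid", axes = c(50, 80, 100),
                                       spacing = c(1, 1, 1), noiseSigma = 0,
                                       seed = 1,
                                       rotation = eulerRotation(
                                         c(1.1, 0.6, 2.0))))
  r <- measureShape3D(rotated$truth@mask)
  for (f in c("sphericity", "roundness", "e1", "e2")) {
    expect_lt(abs(slot(a, f) - slot(b, f)), 0.03)
    expect_lt(abs(slot(r, f) - slot(b, f)), 0.03)
  }
})
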