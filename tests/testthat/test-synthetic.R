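test_that("phantom generation is seeded and its truth is analytic", {
  spec <- phantomSpec("sphere", axes = 100, spacing = c(2, 1.3, 1.3),
                      seed = 7)
  a <- makePhantom3D(spec)
  b <- makePhantom3D(spec)
  expect_identical(imageData(a$grid), imageData(b$grid))

  spec2 <- phantomSpec("sphere", axes = 100, spacing = c(2, 1.3, 1.3),
                       seed = 8)
  c_ <- makePhantom3D(spec2)
  expect_false(identical(imageData(a$grid), imageData(c_$grid)))
  # different noise, same ground truth
  expect_equal(a$truth@volume, c_$truth@volume)
  expect_identical(imageData(a$truth@mask), imageData(c_$truth@mask))

  # phantom generation must not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(makePhantom3D(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("ground-truth closed forms are correct for each shape", {
  # sphere r = 500 um: V = 0.5236 mm^3, sphericity 1, e1 = 0
  s <- makePhantom3D(phantomSpec("sphere", axes = 500, spacing = c(5, 5, 5),
                                 noiseSigma = 0, seed = 1))$truth
  expect_equal(s@volume, (4 / 3) * pi * 0.5^3)
  expect_equal(s@volume, 0.5236, tolerance = 1e-4)
  expect_equal(s@sphericity, 1)
  expect_equal(s@roundness, 1)
  expect_equal(s@e1, 0)
  expect_equal(s@thickness, 1000)

  # half-sphere r = 500: V = 0.2618 mm^3, thickness 500, diameter 1000
  h <- makePhantom3D(phantomSpec("half_sphere", axes = 500,
                                 spacing = c(5, 5, 5), noiseSigma = 0,
                                 seed = 1))$truth
  expect_equal(h@volume, (2 / 3) * pi * 0.5^3)
  expect_equal(h@volume, 0.2618, tolerance = 1e-3)
  expect_equal(h@thickness, 500)
  expect_equal(h@diameter, 1000)
  # analytic surface: hemisphere + base = 3*pi*r^2
  expect_equal(h@surface, 3 * pi * 0.5^2, tolerance = 1e-6)
  expect_equal(h@sphericity, 16 / 27, tolerance = 1e-6)

  # flat-bottomed half oblate cap: V = (2/3) pi a^2 c
  cp <- makePhantom3D(phantomSpec("flat_bottom_cap", axes = c(310, 650, 650),
                                  capHeight = 310, spacing = c(5, 5, 5),
                                  noiseSigma = 0, seed = 1))$truth
  expect_equal(cp@volume, (2 / 3) * pi * 0.65^2 * 0.31, tolerance = 1e-6)
  expect_equal(cp@thickness, 310)
  expect_equal(cp@diameter, 1300)

  # taller-than-hemisphere spherical cap: V = (pi t^2 / 3) (3R - t)
  tall <- makePhantom3D(phantomSpec("flat_bottom_cap", axes = c(180, 180, 180),
                                    capHeight = 265, spacing = c(4, 4, 4),
                                    noiseSigma = 0, seed = 1))$truth
  expect_equal(tall@volume, pi * 0.265^2 * (3 * 0.18 - 0.265) / 3,
               tolerance = 1e-6)
  expect_equal(tall@diameter, 360)  # the equator is included
})

test_that("rasterization error is below 1% for adequately sampled shapes", {
  for (sh in c("sphere", "half_sphere")) {
    ph <- makePhantom3D(phantomSpec(sh, axes = 40, spacing = c(1, 1, 1),
                                    noiseSigma = 0, seed = 1))
    rastVol <- sum(imageData(ph$truth@mask)) / 1e9
    expect_lt(abs(rastVol / ph$truth@volume - 1), 0.01)
  }
  # anisotropic spacing, min axis >= 25 voxels
  ph <- makePhantom3D(phantomSpec("ellipsoid", axes = c(60, 80, 100),
                                  spacing = c(2, 1.3, 1.3), noiseSigma = 0,
                                  seed = 1))
  rastVol <- sum(imageData(ph$truth@mask)) * prod(c(2, 1.3, 1.3)) / 1e9
  expect_lt(abs(rastVol / ph$truth@volume - 1), 0.01)
})

test_that("rasterizeTruth reproduces the stored mask on the native lattice", {
  ph <- makePhantom3D(phantomSpec("ellipsoid", axes = c(30, 40, 50),
                                  spacing = c(2, 1.3, 1.3), noiseSigma = 0,
                                  seed = 2,
                                  rotation = eulerRotation(c(0.4, 1.0, 0.2))))
  again <- rasterizeTruth(ph$truth, c(2, 1.3, 1.3), dim(ph$truth@mask))
  expect_identical(imageData(again), imageData(ph$truth@mask))
})

test_that("the growth series is structured like the measured time course", {
  specs <- growthSeriesSpecs(seed = 2)
  expect_length(specs, 6)
  truths <- lapply(specs, function(s) makePhantom3D(s)$truth)
  diam <- vapply(truths, function(t) t@diameter, numeric(1))
  thick <- vapply(truths, function(t) t@thickness, numeric(1))
  expect_true(all(diff(diam) > 0))           # diameter grows monotonically
  expect_false(all(diff(thick) >= 0))        # thickness peaks then drops
  expect_equal(thick[c(1, 3, 6)], c(265, 390, 310))
  expect_equal(diam[c(1, 3, 6)], c(360, 550, 1300))

  # single-element series is valid
  one <- makeGrowthSeries(specs[3])
  expect_length(one, 1)
  expect_error(makeGrowthSeries(list()), "at least one")
})

test_that("PI phantoms carry their construction truth", {
  pp <- makePIPhantom(deadFraction = 0.4, pattern = "rim", seed = 6)
  expect_equal(pp$truth$deadFraction, 0.4)
  expect_identical(dim(pp$bf), dim(pp$pi))
  # rasterized rim area fraction matches the request closely
  d <- imageData(pp$truth$bfMask)
  rim <- imageData(pp$pi) > 100 & d
  expect_lt(abs(sum(rim) / sum(d) - 0.4), 0.02)
  expect_error(makePIPhantom(deadFraction = 1.2, seed = 1), "0, 1")
})

test_that("phantom specs validate their stated world", {
  expect_error(phantomSpec("cube", axes = 10, seed = 1), "unknown shape")
  expect_error(phantomSpec("ellipsoid", axes = c(-1, 2, 3), seed = 1),
               "positive")
  expect_error(phantomSpec("flat_bottom_cap", axes = c(100, 80, 90),
                           capHeight = 50, seed = 1), "equal lateral")
  expect_error(phantomSpec("flat_bottom_cap", axes = c(100, 80, 80),
                           capHeight = 500, seed = 1), "capHeight")
})
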