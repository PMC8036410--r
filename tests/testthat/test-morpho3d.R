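test_that("isotropic resampling preserves extent, identity and volume", {
  # extent arithmetic: (2.0, 1.3, 1.3) spacing at shape (100, 200, 200)
  # resampled to 1.3 um gives a z size of round(100 * 2.0 / 1.3) = 154
  g <- VoxelGrid(array(0, c(100, 200, 200)), spacing = c(2.0, 1.3, 1.3))
  expect_identical(dim(resampleIsotropic(g, 1.3)), c(154L, 200L, 200L))

  # already-isotropic grid is returned voxelwise identical
  set.seed(5)
  gi <- VoxelGrid(array(runif(20^3), c(20, 20, 20)), spacing = c(2, 2, 2))
  expect_identical(imageData(resampleIsotropic(gi, 2)), imageData(gi))

  # foreground volume of a solid sphere is conserved within 2%
  spec <- phantomSpec("sphere", axes = 40, spacing = c(2, 1.3, 1.3),
                      noiseSigma = 0, seed = 1)
  ph <- makePhantom3D(spec)
  lv <- (10 + 180) / 2
  before <- sum(imageData(ph$grid) > lv) * prod(spacing(ph$grid))
  rs <- resampleIsotropic(ph$grid, 1.3)
  after <- sum(imageData(rs) > lv) * prod(spacing(rs))
  expect_lt(abs(after / before - 1), 0.02)
})

test_that("noise sigma estimation is calibrated, robust and linear", {
  set.seed(4)
  g <- VoxelGrid(array(100 + rnorm(64^3, 0, 10), c(64, 64, 64)),
                 spacing = c(1, 1, 1))
  est <- estimateNoiseSigma(g)
  expect_gt(est, 9); expect_lt(est, 11)

  # noise-free piecewise-constant phantom: edges do not fool the median
  ph <- makePhantom3D(phantomSpec("sphere", axes = 30,
                                  spacing = c(1, 1, 1),
                                  noiseSigma = 0, seed = 1))
  expect_lte(estimateNoiseSigma(ph$grid), 0.5)

  # doubling intensities doubles the estimate
  g2 <- VoxelGrid(2 * imageData(g), spacing = c(1, 1, 1))
  expect_lt(abs(estimateNoiseSigma(g2) / (2 * est) - 1), 0.05)

  expect_error(estimateNoiseSigma(
    VoxelGrid(array(0, c(4, 4, 4)), c(1, 1, 1))), "8x8x8")
})

test_that("non-local means denoising suppresses noise, preserves signal", {
  spec <- phantomSpec("sphere", axes = 40, spacing = c(1, 1, 1),
                      noiseSigma = 15, seed = 11)
  ph <- makePhantom3D(spec)
  g <- ph$grid

  # strength 0 is the identity
  expect_identical(imageData(denoiseNLM(g, sigma = 15, strength = 0)),
                   imageData(g))

  gd <- denoiseNLM(g, sigma = 15)
  bg <- !imageData(ph$truth@mask)
  expect_gt(sd(imageData(g)[bg]) / sd(imageData(gd)[bg]), 2)
  expect_lt(abs(mean(imageData(gd)) / mean(imageData(g)) - 1), 0.01)
})

test_that("hysteresis thresholding equals the flood-fill contract", {
  # hand-traced 1D case: values (0, 5, 9, 2, 0), low 4, high 8
  g <- VoxelGrid(array(c(0, 5, 9, 2, 0), c(5, 1, 1)), spacing = c(1, 1, 1))
  m <- hysteresisSegment(g, low = 4, high = 8)
  expect_identical(as.logical(imageData(m)),
                   c(FALSE, TRUE, TRUE, FALSE, FALSE))

  # all voxels below low: empty mask
  expect_false(any(imageData(hysteresisSegment(g, low = 20, high = 30))))

  # low == high degenerates to single thresholding
  set.seed(9)
  a <- array(runif(10^3), c(10, 10, 10))
  ga <- VoxelGrid(a, c(1, 1, 1))
  expect_identical(imageData(hysteresisSegment(ga, 0.5, 0.5)),
                   array(a >= 0.5, dim(a)))

  expect_error(hysteresisSegment(g, low = 9, high = 4), "low")
})

test_that("the full 3D pipeline recovers a bivariate sphere phantom", {
  # homogeneous bright sphere, r = 60 voxels, SNR 6, anisotropic spacing
  spec <- phantomSpec("sphere", axes = 60 * 1.3, spacing = c(2, 1.3, 1.3),
                      seed = 21)
  ph <- makePhantom3D(spec)
  m <- segmentSpheroid3D(ph$grid)
  expect_identical(spacing(m), rep(1.3, 3))
  tm <- rasterizeTruth(ph$truth, spacing(m), dim(m))
  expect_gte(diceCoefficient(m, tm), 0.97)
  expect_lt(abs(sum(imageData(m)) * prod(spacing(m)) / 1e9 /
                  ph$truth@volume - 1), 0.03)
})

test_that("the pipeline rejects degenerate inputs", {
  expect_error(segmentSpheroid3D(
    VoxelGrid(array(5, c(16, 16, 16)), c(1, 1, 1))), "constant")

  # pure noise: no contrast above the noise level
  set.seed(2)
  g <- VoxelGrid(array(100 + rnorm(48^3, 0, 20), c(48, 48, 48)),
                 spacing = c(1, 1, 1))
  expect_error(segmentSpheroid3D(g), "empty segmentation")

  # a real but tiny object fails the component-size floor
  a <- array(10, c(32, 32, 32))
  a[15:18, 15:18, 15:18] <- 200
  set.seed(3)
  a <- a + rnorm(length(a), 0, 2)
  expect_error(segmentSpheroid3D(VoxelGrid(a, c(1, 1, 1))),
               "below the minimum")
})
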