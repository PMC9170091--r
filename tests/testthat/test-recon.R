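test_that("a consistent image is an EM fixed point", {
  geo <- acquisitionGeometry(nAngles = 20, detectorBins = 32, binSize = 6)
  set.seed(3)
  init <- matrix(runif(256) + 0.5, 16, 16)
  mu0 <- matrix(0, 16, 16)
  y <- idealForwardProject(init, mu0, geo, voxelSize = 6) / 20
  img <- osem(y, mu0, geo, nIterations = 1, nSubsets = 1, voxelSize = 6,
              initial = init)
  expect_lt(max(abs(reconValues(img) - init) / init), 1e-6)
})

test_that("MLEM conserves total counts when mu = 0", {
  geo <- acquisitionGeometry(nAngles = 20, detectorBins = 32, binSize = 6)
  set.seed(4)
  truth <- matrix(runif(256), 16, 16)
  mu0 <- matrix(0, 16, 16)
  y <- idealForwardProject(truth, mu0, geo, voxelSize = 6) / 20
  prev <- matrix(1, 16, 16)
  for (it in 1:3) {
    img <- osem(y, mu0, geo, 1, 1, voxelSize = 6, initial = prev)
    prev <- reconValues(img)
    expect_lt(abs(sum(prev) - sum(y)) / sum(y), 1e-6)
  }
})

test_that("NRMSE to truth decreases monotonically on noise-free data", {
  n <- 32
  geo <- acquisitionGeometry(nAngles = 30, detectorBins = 48, binSize = 6.4)
  truth <- matrix(0, n, n)
  truth[spectscatter:::circleMask(n, 6.4, 120)] <- 50
  truth[16, 16] <- 500; truth[10, 20] <- 200
  mu <- matrix(0, n, n)
  mu[spectscatter:::circleMask(n, 6.4, 150)] <- 0.1
  y <- oracleForwardProject(truth, mu, 6.4, geo) / 30   # oracle projector
  prev <- matrix(1, n, n)
  errs <- numeric(50)
  for (it in 1:50) {
    prev <- reconValues(osem(y, mu, geo, 1, 1, voxelSize = 6.4,
                             initial = prev))
    errs[it] <- nrmse(prev, truth)
  }
  expect_true(all(diff(errs) <= 1e-10))
  expect_lt(errs[50], 0.25)
})

test_that("subset orderings agree at convergence", {
  n <- 32
  geo <- acquisitionGeometry(nAngles = 30, detectorBins = 48, binSize = 6.4)
  truth <- matrix(0, n, n)
  truth[spectscatter:::circleMask(n, 6.4, 120)] <- 50
  truth[16, 16] <- 500
  mu <- matrix(0, n, n)
  mu[spectscatter:::circleMask(n, 6.4, 150)] <- 0.1
  y <- idealForwardProject(truth, mu, geo, voxelSize = 6.4) / 30
  i1 <- osem(y, mu, geo, 150, 1, voxelSize = 6.4)
  i15 <- osem(y, mu, geo, 10, 15, voxelSize = 6.4)
  expect_lt(nrmse(reconValues(i15), reconValues(i1)), 0.02)
})

test_that("osem validates its inputs and records its protocol", {
  geo <- acquisitionGeometry(nAngles = 20, detectorBins = 32, binSize = 6)
  y <- matrix(1, 20, 32)
  mu0 <- matrix(0, 16, 16)
  expect_error(osem(y, mu0, geo, nSubsets = 7, voxelSize = 6), "divide")
  expect_error(osem(y * 0, mu0, geo, voxelSize = 6), "all-zero")
  expect_error(osem(y - 2, mu0, geo, voxelSize = 6), "nonnegative")
  img <- osem(y, mu0, geo, 2, 5, voxelSize = 6, psfFwhm = 8)
  expect_true(all(reconValues(img) >= 0))
  expect_equal(reconMeta(img)$iterations, 2)
  expect_equal(reconMeta(img)$subsets, 5)
  expect_equal(reconMeta(img)$psf_fwhm, 8)
  expect_equal(reconMeta(img)$scatter_model, "none")
})

test_that("additive ground-truth scatter modeling improves the background", {
  # line source in water: reconstruct uncorrected vs with the simulator's
  # true scatter as the additive term; the corrected background must be
  # closer to the air-reference reconstruction
  geo <- testGeometry(detectorBins = 64)
  pw <- buildTLSP("water", gridSize = 65, voxelSize = 4.8)
  pa <- buildTLSP("air", gridSize = 65, voxelSize = 4.8)
  ww <- simulateProjections(pw, geometry = geo, histories = 5e5, seed = 41)
  wa <- simulateProjections(pa, geometry = geo, histories = 5e5, seed = 42)
  ref <- reconValues(osem(windowCounts(wa, "main"), attenuationMap(pa), geo,
                          2, 15, voxelSize = 4.8))
  un <- reconValues(osem(windowCounts(ww, "main"), attenuationMap(pw), geo,
                         2, 15, voxelSize = 4.8))
  co <- reconValues(osem(windowCounts(ww, "main"), attenuationMap(pw), geo,
                         2, 15, voxelSize = 4.8,
                         scatterAdditive = trueScatter(ww)))
  expect_lt(nrmse(co, ref), nrmse(un, ref))
})

test_that("calibration recovers the known concentration scale", {
  uni <- buildUniformCylinder(gridSize = 33, voxelSize = 9.6)
  conc <- sum(phantomActivity(uni)) /
    (sum(phantomActivity(uni) > 0) * 9.6^3 / 1000)
  roi <- circularROI(100)
  exact <- new("ReconImage", values = matrix(conc, 33, 33), voxelSize = 9.6,
               meta = list())
  expect_equal(calibrate(exact, uni, roi), 1)
  halved <- new("ReconImage", values = matrix(2 * conc, 33, 33),
                voxelSize = 9.6, meta = list())
  expect_equal(calibrate(halved, uni, roi), 0.5)
  zero <- new("ReconImage", values = matrix(0, 33, 33), voxelSize = 9.6,
              meta = list())
  expect_error(calibrate(zero, uni, roi), "zero mean")
})
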