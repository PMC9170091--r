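mkImage <- function(values, voxelSize = 4.8)
  new("ReconImage", values = values, voxelSize = voxelSize,
      meta = list())

test_that("ROI counts equal the brute-force masked sum", {
  set.seed(12)
  img <- mkImage(matrix(rexp(65 * 65), 65, 65))
  roi <- circularROI(150)
  expect_equal(roiCounts(img, roi),
               oracleMaskedSum(reconValues(img), 4.8, 150))
  # uniform image of 1: T = number of pixels inside
  ones <- mkImage(matrix(1, 65, 65))
  expect_equal(roiCounts(ones, roi), oracleCircleCount(65, 4.8, 150))
  expect_equal(roiCounts(mkImage(matrix(0, 65, 65)), roi), 0)
  # list input averages over realizations (the 2D 10-slice surrogate)
  expect_equal(roiCounts(list(ones, mkImage(matrix(3, 65, 65))), roi),
               2 * oracleCircleCount(65, 4.8, 150))
  expect_error(roiCounts(ones, circularROI(400)), "outside")
})

test_that("scatter fraction follows the reference-ratio definition", {
  expect_equal(scatterFraction(100, 100), 0)
  expect_equal(scatterFraction(120, 100), 100 / 6, tolerance = 1e-12)
  expect_equal(scatterFraction(90, 100), -100 / 9, tolerance = 1e-12)
  expect_error(scatterFraction(0, 100))
})

test_that("NMSE matches its definition and the direct-summation oracle", {
  expect_equal(nmse(rep(5, 10), rep(5, 10)), 0)
  expect_equal(nmse(rep(100, 7), rep(110, 7)), 1.0)
  set.seed(99)
  a <- rexp(400); b <- rexp(400)
  expect_equal(nmse(a, b), oracleNMSE(a, b), tolerance = 1e-12)
  expect_error(nmse(a, b[1:10]))
  expect_error(nmse(rep(0, 4), rep(1, 4)))
})

test_that("CV uses the population SD and is scale invariant", {
  img <- mkImage(matrix(1, 33, 33), 9.6)
  roi <- circularROI(120)
  expect_equal(as.numeric(cv(img, roi)), 0)
  # hand-computed two-convention check on {90, 100, 110}
  px <- c(90, 100, 110)
  sdPop <- sqrt(mean((px - mean(px))^2))
  expect_equal(sdPop / mean(px) * 100, 8.1649658, tolerance = 1e-6)
  expect_equal(sd(px) / mean(px) * 100, 10.0, tolerance = 1e-6)
  m <- matrix(100, 33, 33); m[16, 16] <- 90; m[17, 17] <- 110
  got <- cv(mkImage(m, 9.6), roi)
  expect_equal(attr(got, "sd_convention"), "population")
  n <- sum(spectscatter:::circleMask(33, 9.6, 120))
  pxAll <- c(rep(100, n - 2), 90, 110)
  expect_equal(as.numeric(got),
               sqrt(mean((pxAll - mean(pxAll))^2)) / mean(pxAll) * 100,
               tolerance = 1e-12)
  # scale invariance
  expect_equal(as.numeric(cv(mkImage(3.7 * m, 9.6), roi)),
               as.numeric(got), tolerance = 1e-12)
  expect_error(cv(mkImage(matrix(0, 33, 33), 9.6), roi), "zero mean")
})

test_that("residual images are elementwise differences", {
  a <- mkImage(matrix(runif(16), 4, 4), 4.8)
  expect_equal(residualImage(a, a), matrix(0, 4, 4))
  b <- mkImage(reconValues(a) + 5, 4.8)
  expect_equal(residualImage(b, a), matrix(5, 4, 4))
  expect_error(residualImage(a, mkImage(matrix(0, 3, 3), 4.8)))
  expect_error(residualImage(a, mkImage(reconValues(a), 9.6)),
               "voxel size")
})

test_that("residual-scatter images rank corrections against DEW20", {
  # the scatter left by no correction must exceed the scatter left by
  # TEW10, both measured against the DEW20 reference image
  geo <- testGeometry(detectorBins = 64)
  p <- buildTLSP("water", gridSize = 65, voxelSize = 4.8)
  wp <- simulateProjections(p, geometry = geo, histories = 5e5, seed = 55)
  rec <- function(method) {
    co <- applyCorrection(wp, estimateScatter(wp, method))
    osem(co$counts, attenuationMap(p), geo, 2, 15, voxelSize = 4.8)
  }
  ref <- rec("dew20")
  rNone <- residualImage(rec("none"), ref)
  rTew <- residualImage(rec("tew10"), ref)
  expect_gt(sum(abs(rNone)), sum(abs(rTew)))
})
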