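test_that("Compton kinematics follow the closed-form energy shift", {
  expect_equal(comptonEnergy(140, 0), 140)
  expect_equal(comptonEnergy(140, pi), 140 / (1 + 280 / 511),
               tolerance = 1e-12)
  set.seed(11)
  s <- sampleCompton(2000, 140)
  expect_equal(s$energy, comptonEnergy(140, s$theta), tolerance = 1e-12)
  expect_true(all(s$energy <= 140 & s$energy >= 140 / (1 + 280 / 511)))
})

test_that("sampled scattering angles match the Klein-Nishina density", {
  set.seed(202)
  th <- sampleCompton(2e5, 140)$theta
  Z <- integrate(oracleKNDensity, 0, pi)$value
  br <- seq(0, pi, length.out = 41)
  obs <- hist(th, breaks = br, plot = FALSE)$counts
  p <- vapply(seq_len(40), function(i)
    integrate(oracleKNDensity, br[i], br[i + 1])$value / Z, 0)
  chi2 <- sum((obs - 2e5 * p)^2 / (2e5 * p))
  expect_lt(chi2, qchisq(0.999, df = 39))
})

test_that("energy resolution model is an unbiased Gaussian with 9.8% FWHM", {
  expect_equal(applyEnergyResolution(c(100, 140), r140 = 0), c(100, 140))
  set.seed(5)
  e <- applyEnergyResolution(rep(140, 1e5))
  expect_lt(abs(mean(e) - 140), 0.1)
  expect_lt(abs(sd(e) * 2.3548200450309493 - 13.72) / 13.72, 0.02)
})

test_that("simulation is seed-deterministic with exact scatter bookkeeping", {
  p <- buildTLSP("water", gridSize = 33, voxelSize = 9.6)
  geo <- testGeometry(detectorBins = 32, binSize = 9.6)
  wp1 <- simulateProjections(p, geometry = geo, histories = 5e4, seed = 123)
  wp2 <- simulateProjections(p, geometry = geo, histories = 5e4, seed = 123)
  expect_identical(windowCounts(wp1, "main"), windowCounts(wp2, "main"))
  expect_identical(trueScatter(wp1), trueScatter(wp2))
  # main window decomposes exactly into primary + scatter
  expect_identical(windowCounts(wp1, "main"),
                   truePrimary(wp1) + trueScatter(wp1))
  # counts are nonnegative integers
  for (nm in names(wp1@counts)) {
    m <- windowCounts(wp1, nm)
    expect_true(all(m >= 0 & m == round(m)))
  }
})

test_that("disjoint windows tally each photon at most once", {
  p <- buildTLSP("water", gridSize = 33, voxelSize = 9.6)
  geo <- testGeometry(detectorBins = 32, binSize = 9.6)
  # main + the two TEW 10% flankers are mutually disjoint and cover
  # [112, 168): their sum cannot exceed the detected-photon total
  wins <- c(list(main = mainWindow()), tewSubWindows(0.10))
  wp <- simulateProjections(p, windows = wins, geometry = geo,
                            histories = 5e4, seed = 3)
  total <- sum(windowCounts(wp, "main")) +
    sum(windowCounts(wp, "tew10_lower")) +
    sum(windowCounts(wp, "tew10_upper"))
  expect_lte(total, sum(wp@spectrum))
})

test_that("scatter grows with background density and vanishes in air", {
  geo <- testGeometry(detectorBins = 64)
  ratios <- vapply(c("air", "water", "k2hpo4"), function(m) {
    p <- buildTLSP(m, gridSize = 65, voxelSize = 4.8)
    wp <- simulateProjections(p, geometry = geo, histories = 1e6, seed = 77)
    sum(trueScatter(wp)) / sum(windowCounts(wp, "main"))
  }, 0)
  expect_lt(ratios[["air"]], 0.02)
  expect_gt(ratios[["water"]], ratios[["air"]])
  expect_gt(ratios[["k2hpo4"]], ratios[["air"]])
  # maxOrder = 0 transports primaries only
  p <- buildTLSP("water", gridSize = 33, voxelSize = 9.6)
  wp0 <- simulateProjections(p, geometry = testGeometry(detectorBins = 32,
                                                        binSize = 9.6),
                             histories = 2e4, maxOrder = 0, seed = 5)
  expect_equal(sum(trueScatter(wp0)), 0)
})

test_that("detected energy spectrum peaks at the photopeak", {
  p <- buildTLSP("water", gridSize = 65, voxelSize = 4.8)
  wp <- simulateProjections(p, geometry = testGeometry(), histories = 2e5,
                            seed = 9)
  mids <- (wp@spectrumBreaks[-1] + head(wp@spectrumBreaks, -1)) / 2
  mode <- mids[which.max(wp@spectrum)]
  expect_lt(abs(mode - 140), 0.098 * 140)   # within one FWHM
})

test_that("ideal forward projector obeys point-source closed forms", {
  n <- 129; v <- 2
  geo <- acquisitionGeometry(nAngles = 24, detectorBins = 161, binSize = 2)
  act <- matrix(0, n, n); act[65, 65] <- 100
  # mu = 0: exactly one ray per angle, angle-constant totals
  s0 <- idealForwardProject(act, matrix(0, n, n), geo, voxelSize = v)
  expect_true(all(rowSums(s0 > 0) == 1))
  expect_equal(rowSums(s0), rep(100, 24), tolerance = 1e-12)
  # uniform mu disc: Beer-Lambert exp(-mu R) at every angle
  mu <- matrix(0, n, n)
  mu[spectscatter:::circleMask(n, v, 200)] <- 0.151
  s1 <- idealForwardProject(act, mu, geo, voxelSize = v)
  expect_equal(rowSums(s1), rep(100 * exp(-0.151 * 10), 24),
               tolerance = 0.03)
})

test_that("projector agrees with the brute-force R oracle", {
  set.seed(8)
  n <- 12
  img <- matrix(rexp(n * n), n, n)
  mu <- matrix(runif(n * n, 0, 0.2), n, n)
  geo <- acquisitionGeometry(nAngles = 10, detectorBins = 20, binSize = 8)
  got <- idealForwardProject(img, mu, geo, voxelSize = 8)
  want <- oracleForwardProject(img, mu, 8, geo)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("Monte-Carlo primaries match the analytic projector", {
  p <- buildTLSP("water", gridSize = 65, voxelSize = 4.8)
  geo <- testGeometry(detectorBins = 64)
  wp <- simulateProjections(p, geometry = geo, histories = 2e6, seed = 3)
  ana <- idealForwardProject(p, geometry = geo)
  mc <- truePrimary(wp)
  ana <- ana / sum(ana); mc <- mc / sum(mc)
  expect_lt(sqrt(mean((ana - mc)^2)) / max(ana), 0.03)
})

test_that("repeated-seed counts are Poisson (variance tracks mean)", {
  uni <- buildUniformCylinder(gridSize = 33, voxelSize = 9.6)
  geo <- testGeometry(detectorBins = 32, binSize = 9.6)
  cs <- vapply(1:200, function(s)
    windowCounts(simulateProjections(uni, geometry = geo, histories = 5e4,
                                     seed = s), "main")[15, 16], 0)
  m <- mean(cs); v <- var(cs)
  z <- (v - m) / (m * sqrt(2 / 199))   # sampling sd of a Poisson variance
  expect_lt(abs(z), 3)
})
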