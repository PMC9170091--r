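test_that("energy windows have the declared widths and placement", {
  main <- mainWindow()
  expect_equal(c(main@lower, main@upper), c(126, 154))
  d20 <- dewSubWindow(0.20)
  expect_equal(d20@upper, 126)            # abuts the photopeak from below
  expect_equal(d20@upper - d20@lower, 28)
  tw <- tewSubWindows(0.07)
  expect_equal(tw[[1]]@upper, 126)
  expect_equal(tw[[2]]@lower, 154)
  expect_equal(tw[[1]]@upper - tw[[1]]@lower, 0.07 * 140)
  ws <- defaultWindowSet()
  expect_equal(names(ws)[1], "main")
  expect_lte(length(ws), 16)              # simultaneous-window limit
  expect_error(energyWindow("bad", 100, -0.1))
})

test_that("DEW estimate scales the Compton window by k", {
  expect_equal(scatterValues(dewEstimate(matrix(30), k = 1)),
               matrix(30))
  expect_equal(scatterValues(dewEstimate(matrix(0), k = 1)), matrix(0))
  expect_equal(scatterValues(dewEstimate(matrix(c(3, 5)), k = 2)),
               matrix(c(6, 10)))
  expect_error(dewEstimate(matrix(-1)))
  expect_error(dewEstimate(matrix(1), k = 0))
})

test_that("TEW multipliers reproduce the published table", {
  expect_equal(round(tewK(0.20, 0.03), 1), 3.3)
  expect_equal(tewK(0.20, 0.05), 2.0)
  expect_equal(round(tewK(0.20, 0.07), 1), 1.4)
  expect_equal(tewK(0.20, 0.10), 1.0)
  expect_error(tewK(0.20, 0))
})

test_that("TEW estimate is the trapezoid of the flanking windows", {
  expect_equal(scatterValues(tewEstimate(matrix(10), matrix(2), 2.0)),
               matrix(24))
  expect_equal(scatterValues(tewEstimate(matrix(0), matrix(0), 2.0)),
               matrix(0))
  expect_error(tewEstimate(matrix(1), matrix(1:2, 1), 2.0))
  expect_error(tewEstimate(matrix(-1), matrix(1), 2.0))
})

test_that("TEW is exact for spectra linear across the three windows", {
  # scatter spectrum S(E) = a + b E across [lower sub, main, upper sub];
  # independent oracle: numeric integration of S over the main window
  for (f in c(0.03, 0.05, 0.07, 0.10)) {
    wsub <- f * 140
    S <- function(E) 40 - 0.2 * E
    cLower <- integrate(S, 126 - wsub, 126)$value
    cHigher <- integrate(S, 154, 154 + wsub)$value
    truth <- integrate(S, 126, 154)$value
    k <- tewK(0.20, f)
    est <- scatterValues(tewEstimate(matrix(cLower), matrix(cHigher), k))
    expect_equal(est[1, 1], truth, tolerance = 1e-6)
  }
})

test_that("estimate totals are monotone in k and in the input counts", {
  set.seed(21)
  for (rep in 1:5) {
    sub <- matrix(rpois(60, 20), 6, 10)
    expect_lte(sum(scatterValues(dewEstimate(sub, k = 0.5))),
               sum(scatterValues(dewEstimate(sub, k = 1.0))))
    more <- sub + matrix(rpois(60, 5), 6, 10)
    expect_lte(sum(scatterValues(dewEstimate(sub, k = 1))),
               sum(scatterValues(dewEstimate(more, k = 1))))
    lo <- matrix(rpois(60, 15), 6, 10); hi <- matrix(rpois(60, 5), 6, 10)
    expect_lte(sum(scatterValues(tewEstimate(lo, hi, 2))),
               sum(scatterValues(tewEstimate(lo + 1, hi, 2))))
    expect_lte(sum(scatterValues(tewEstimate(lo, hi, 2))),
               sum(scatterValues(tewEstimate(lo, hi + 1, 2))))
  }
})

test_that("correction subtracts with a zero clip and counts clipped bins", {
  co <- applyCorrection(matrix(100), dewEstimate(matrix(30)))
  expect_equal(co$counts, matrix(70))
  expect_equal(clippedBins(co$estimate), 0)
  co2 <- applyCorrection(matrix(10), dewEstimate(matrix(25)))
  expect_equal(co2$counts, matrix(0))
  expect_equal(clippedBins(co2$estimate), 1)
  # zero estimate is the identity
  y <- matrix(rpois(12, 50), 3, 4)
  co3 <- applyCorrection(y, dewEstimate(y * 0))
  expect_equal(co3$counts, y * 1)
  # additive mode passes data through and forwards the estimate
  co4 <- applyCorrection(y, dewEstimate(y * 0 + 5), mode = "additive_model")
  expect_identical(co4$counts, y)
  expect_equal(co4$scatterAdditive, y * 0 + 5)
  expect_error(applyCorrection(matrix(1), dewEstimate(matrix(1:2, 1))))
})

test_that("DEW estimate grows with nested sub-window width on simulation", {
  p <- buildTLSP("water", gridSize = 65, voxelSize = 4.8)
  wp <- simulateProjections(p, geometry = testGeometry(), histories = 3e5,
                            seed = 31)
  tot <- vapply(c("dew5", "dew10", "dew15", "dew20"), function(m)
    sum(scatterValues(estimateScatter(wp, m))), 0)
  expect_true(all(diff(tot) >= 0))
})

test_that("method dispatcher covers the evaluated corrections", {
  p <- buildTLSP("water", gridSize = 33, voxelSize = 9.6)
  geo <- testGeometry(detectorBins = 32, binSize = 9.6)
  wp <- simulateProjections(p, geometry = geo, histories = 5e4, seed = 13)
  expect_equal(sum(scatterValues(estimateScatter(wp, "none"))), 0)
  expect_identical(scatterValues(estimateScatter(wp, "truth")),
                   trueScatter(wp))
  e <- estimateScatter(wp, "tew5")
  expect_equal(e@params$k_lower, 2.0)
  expect_error(estimateScatter(wp, "dtw7"), "unknown")
  expect_error(estimateScatter(wp, "esse"), "requires")
})
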