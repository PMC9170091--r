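# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities with naive loops / closed forms rather than calling
# the package's optimized paths.

# pixel-counting rasterization of a circle: number of pixel centers inside
oracleCircleCount <- function(n, voxelSize, diameterMM, centerMM = c(0, 0)) {
  cnt <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- (j - (n + 1) / 2) * voxelSize - centerMM[1]
    y <- (i - (n + 1) / 2) * voxelSize - centerMM[2]
    if (x^2 + y^2 <= (diameterMM / 2)^2) cnt <- cnt + 1L
  }
  cnt
}

# masked sum by explicit double loop
oracleMaskedSum <- function(img, voxelSize, diameterMM, centerMM = c(0, 0)) {
  n <- nrow(img)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- (j - (n + 1) / 2) * voxelSize - centerMM[1]
    y <- (i - (n + 1) / 2) * voxelSize - centerMM[2]
    if (x^2 + y^2 <= (diameterMM / 2)^2) s <- s + img[i, j]
  }
  s
}

# NMSE by explicit double summation
oracleNMSE <- function(air, med) {
  num <- 0; den <- 0
  for (k in seq_along(air)) {
    num <- num + (air[k] - med[k])^2
    den <- den + air[k]^2
  }
  num / den * 100
}

# Klein-Nishina polar-angle density (unnormalized): cross-section x sin
oracleKNDensity <- function(theta, E = 140) {
  a <- E / 511
  r <- 1 / (1 + a * (1 - cos(theta)))
  r^2 * (r + 1 / r - sin(theta)^2) * sin(theta)
}

# Brute-force attenuated pixel-driven projector replicating the declared
# discrete model (linear bin interpolation, midpoint attenuation marching)
# in plain R loops.
oracleForwardProject <- function(img, mu, voxelSize, geometry,
                                 stepFrac = 0.25) {
  n <- nrow(img)
  nAng <- geometry@nAngles
  nb <- geometry@detectorBins
  angles <- (seq_len(nAng) - 1) * geometry@arc / nAng * pi / 180
  half <- n * voxelSize / 2
  step <- voxelSize * stepFrac
  out <- matrix(0, nAng, nb)
  for (a in seq_len(nAng)) {
    ux <- cos(angles[a]); uy <- sin(angles[a])
    for (j in seq_len(n)) for (i in seq_len(n)) {
      if (img[i, j] <= 0) next
      x0 <- (j - (n + 1) / 2) * voxelSize
      y0 <- (i - (n + 1) / 2) * voxelSize
      acc <- 0; t <- step / 2
      repeat {
        x <- x0 + ux * t; y <- y0 + uy * t
        if (abs(x) >= half || abs(y) >= half) break
        ii <- floor(y / voxelSize + n / 2) + 1
        jj <- floor(x / voxelSize + n / 2) + 1
        acc <- acc + mu[min(max(ii, 1), n), min(max(jj, 1), n)] / 10
        t <- t + step
      }
      val <- img[i, j] * exp(-acc * step)
      tt <- (-x0 * sin(angles[a]) + y0 * cos(angles[a])) /
        geometry@binSize + (nb - 1) / 2
      b0 <- floor(tt); w <- tt - b0
      if (b0 >= 0 && b0 < nb) out[a, b0 + 1] <- out[a, b0 + 1] + val * (1 - w)
      if (b0 + 1 >= 0 && b0 + 1 < nb) out[a, b0 + 2] <- out[a, b0 + 2] + val * w
    }
  }
  out
}

nrmse <- function(x, ref) sqrt(mean((x - ref)^2)) / sqrt(mean(ref^2))

# small shared geometry for fast tests
testGeometry <- function(nAngles = 60, detectorBins = 64, binSize = 4.8)
  acquisitionGeometry(nAngles = nAngles, detectorBins = detectorBins,
                      binSize = binSize)
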