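# Effective-scatter-source (ESSE-style) correction.  The vendor kernels are
# proprietary, so the kernels here are fitted to this package's own
# Monte-Carlo point responses in water and shipped as regenerable code paths.

#' Monte-Carlo point-source scatter profiles at several depths
#'
#' Simulates a point source at several lateral offsets inside a water
#' cylinder and records, for the gantry angle whose detector normal is +x,
#' the main-window scatter profile across detector bins together with the
#' primary/scatter totals.  These profiles are the fitting input for
#' [esseFitKernels()].
#'
#' @param depthsMM source offsets from the cylinder center along +x, mm.
#' @param histories photon histories per depth.
#' @param seed base RNG seed (one increment per depth).
#' @param gridSize,voxelSize phantom grid, voxels / mm.
#' @param diameterMM water cylinder diameter, mm.
#' @param geometry an [AcquisitionGeometry-class].
#' @param materials material catalogue.
#' @return list with one entry per depth: `depth`, `profile` (scatter counts
#'   per bin), `scatterTotal`, `primaryTotal`, `binSize`.
#' @export
essePointResponses <- function(depthsMM = c(0, 40, 80), histories = 1e6,
                               seed = 1, gridSize = 64, voxelSize = 4.8,
                               diameterMM = 200,
                               geometry = acquisitionGeometry(detectorBins = 64),
                               materials = materialTable()) {
  if (length(depthsMM) < 3) stop("need >= 3 depths of point responses")
  n <- as.integer(gridSize)
  lapply(seq_along(depthsMM), function(ii) {
    d <- depthsMM[ii]
    labels <- matrix(match("air", materials$name), n, n)
    labels[circleMask(n, voxelSize, diameterMM)] <- match("water",
                                                          materials$name)
    act <- matrix(0, n, n)
    j <- round(d / voxelSize + (n + 1) / 2)
    i <- centralIndex(n)
    act[i, j] <- 1e6
    ph <- newPhantom(act, labels, voxelSize, sprintf("point_d%g", d),
                     materials)
    wp <- simulateProjections(ph, windows = list(main = mainWindow()),
                              geometry = geometry, histories = histories,
                              seed = seed + ii - 1)
    list(depth = d, profile = trueScatter(wp)[1, ],
         scatterTotal = sum(trueScatter(wp)),
         primaryTotal = sum(truePrimary(wp)),
         binSize = geometry@binSize, diameterMM = diameterMM,
         gridSize = n, voxelSize = voxelSize,
         muMedium = materials$mu_140[materials$name == "water"])
  })
}

# Broad normalized Gaussian kernel (FWHM in mm) on the voxel grid; used as
# the relative-scatter-attenuation kernel: conv(mu, G)/muRef measures how
# much scattering material surrounds a voxel, hence its scatter yield.
attnKernelMatrix <- function(fwhmMM, voxelSize) {
  sigma <- fwhmMM / 2.3548200450309493
  h <- max(1L, ceiling(3 * sigma / voxelSize))
  idx <- (-h):h
  r2 <- outer(idx^2, idx^2, `+`) * voxelSize^2
  k <- exp(-r2 / (2 * sigma^2))
  k / sum(k)
}

# Normalized radial shape: Gaussian core + exponential tail.
esseShape <- function(s, sigma, tau, beta) {
  (1 - beta) * stats::dnorm(s, 0, sigma) + beta * exp(-abs(s) / tau) / (2 * tau)
}

#' Fit ESSE convolution kernels to Monte-Carlo point responses
#'
#' Least-squares fit of a shared radially symmetric shape — a Gaussian core
#' plus an exponential tail, `(1-beta) N(0, sigma) + beta Laplace(tau)` —
#' to the scatter profiles of [essePointResponses()], with one free
#' amplitude per depth.  The kernel normalization is taken from the measured
#' scatter-to-primary ratio, so convolving an activity estimate with the
#' kernel and forward-projecting reproduces the scatter magnitude of the
#' calibration geometry.
#'
#' @param responses list from [essePointResponses()] (or any list of
#'   `list(depth=, profile=, ...)` entries; >= 3 depths).
#' @param energy photon energy the kernels apply to, keV.
#' @param muRef reference attenuation of the fitting medium, cm^-1.
#' @return list of class `esseKernels`: `sigma`, `tau`, `beta` (mm and
#'   dimensionless), `s2p` (scatter-to-primary ratio), `residualRMS`,
#'   `peak`, `energy`, `muRef`, `depths`, `amplitudes`.
#' @export
esseFitKernels <- function(responses, energy = 140, muRef = 0.151) {
  if (length(responses) < 3) stop("insufficient depths (need >= 3)")
  binSize <- responses[[1]]$binSize %||% 4.8
  profiles <- lapply(responses, function(r) as.numeric(r$profile))
  nb <- length(profiles[[1]])
  s <- (seq_len(nb) - (nb + 1) / 2) * binSize
  nd <- length(profiles)

  rss <- function(sigma, tau, beta) {
    g <- esseShape(s, sigma, tau, beta) * binSize
    gg <- sum(g * g)
    if (gg <= 0) return(Inf)
    sum(vapply(profiles, function(p) {
      m <- max(0, sum(p * g) / gg)       # profile-wise amplitude, closed form
      sum((p - m * g)^2)
    }, 0))
  }
  # moment-based init for sigma from the pooled profile
  pooled <- Reduce(`+`, profiles)
  pooled[pooled < 0] <- 0
  s0 <- sqrt(max(sum(pooled * s^2) / max(sum(pooled), 1e-12), binSize^2))
  obj <- function(par) rss(exp(par[1]), exp(par[2]), stats::plogis(par[3]))
  fit <- stats::optim(c(log(s0), log(2 * s0), stats::qlogis(0.05)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  sigma <- exp(fit$par[1]); tau <- exp(fit$par[2])
  beta <- stats::plogis(fit$par[3])
  if (!is.finite(fit$value)) stop("non-finite kernel fit")

  g <- esseShape(s, sigma, tau, beta) * binSize
  amps <- vapply(profiles, function(p) max(0, sum(p * g) / sum(g * g)), 0)
  resid <- unlist(Map(function(p, m) p - m * g, profiles, as.list(amps)))
  sTot <- sum(vapply(responses, function(r) r$scatterTotal %||% sum(r$profile), 0))
  pTot <- sum(vapply(responses, function(r) r$primaryTotal %||% NA_real_, 0))
  depths <- vapply(responses, function(r) r$depth, 0)

  # Relative scatter attenuation: the per-depth scatter-to-primary ratio is
  # modeled as s2p(d) = s2pScale * W(d), where W = conv(mu, G_fwhm)/muRef
  # measures the scattering material around the source.  Fit the kernel
  # width (fwhm) and scale to the measured per-depth ratios when the
  # responses carry their calibration geometry.
  s2pD <- vapply(responses, function(r) {
    if (is.null(r$scatterTotal) || is.null(r$primaryTotal) ||
        r$primaryTotal <= 0) NA_real_ else r$scatterTotal / r$primaryTotal
  }, 0)
  attnFwhm <- NA_real_
  s2pScale <- if (all(is.na(s2pD))) NA_real_ else mean(s2pD, na.rm = TRUE)
  r1 <- responses[[1]]
  if (!any(is.na(s2pD)) && !is.null(r1$diameterMM) &&
      !is.null(r1$gridSize) && !is.null(r1$voxelSize)) {
    n <- r1$gridSize
    muGrid <- matrix(0, n, n)
    muGrid[circleMask(n, r1$voxelSize, r1$diameterMM)] <-
      r1$muMedium %||% muRef
    jd <- round(depths / r1$voxelSize + (n + 1) / 2)
    id <- centralIndex(n)
    wAt <- function(fwhm) {
      w <- conv2same(muGrid, attnKernelMatrix(fwhm, r1$voxelSize)) / muRef
      w[cbind(rep(id, length(jd)), jd)]
    }
    loss <- function(fwhm) {
      w <- wAt(fwhm)
      cc <- sum(s2pD * w) / sum(w * w)
      sum((s2pD - cc * w)^2)
    }
    op <- stats::optimize(loss, c(2 * r1$voxelSize, 2 * r1$diameterMM))
    attnFwhm <- op$minimum
    w <- wAt(attnFwhm)
    s2pScale <- sum(s2pD * w) / sum(w * w)
  }

  structure(list(sigma = sigma, tau = tau, beta = beta,
                 s2p = if (is.finite(pTot) && pTot > 0) sTot / pTot else NA_real_,
                 s2pScale = s2pScale, attnFwhm = attnFwhm,
                 residualRMS = sqrt(mean(resid^2)),
                 peak = max(unlist(profiles)),
                 energy = energy, muRef = muRef,
                 depths = depths, s2pByDepth = s2pD,
                 amplitudes = amps),
            class = "esseKernels")
}

#' 2D scatter-source kernel on the voxel grid
#'
#' Radially symmetric discretization of the fitted shape, truncated at
#' `4 * max(sigma, tau)` and normalized so the kernel sums to the
#' scatter-to-primary ratio.
#'
#' @param kernels an `esseKernels` fit.
#' @param voxelSize voxel edge, mm.
#' @param maxRadiusMM truncation cap on the kernel radius, mm.
#' @return odd-sized square matrix.
#' @export
esseKernelMatrix <- function(kernels, voxelSize, maxRadiusMM = 150) {
  rmax <- min(4 * max(kernels$sigma, kernels$tau), maxRadiusMM)
  h <- max(1L, ceiling(rmax / voxelSize))
  idx <- (-h):h
  r <- sqrt(outer(idx^2, idx^2, `+`)) * voxelSize
  k <- esseShape(r, kernels$sigma, kernels$tau, kernels$beta)
  s2p <- if (is.finite(kernels$s2p)) kernels$s2p else 1
  k / sum(k) * s2p
}

# 'same'-size 2D convolution via FFT (kernel must be odd-sized).
conv2same <- function(x, k) {
  n1 <- nrow(x) + nrow(k) - 1
  n2 <- ncol(x) + ncol(k) - 1
  px <- matrix(0, n1, n2); px[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  pk <- matrix(0, n1, n2); pk[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- Re(stats::fft(stats::fft(px) * stats::fft(pk), inverse = TRUE)) /
    (n1 * n2)
  oi <- (nrow(k) - 1) / 2
  oj <- (ncol(k) - 1) / 2
  out <- full[seq_len(nrow(x)) + oi, seq_len(ncol(x)) + oj, drop = FALSE]
  out[abs(out) < 1e-12 * max(abs(out))] <- 0
  pmax(out, 0)
}

#' ESSE-style model-based scatter estimate
#'
#' Each activity voxel is assigned a scatter yield
#' `s2pScale * conv(mu, G)/muRef` — the relative-scatter-attenuation kernel
#' `G` (a broad Gaussian fitted in [esseFitKernels()]) measures how much
#' scattering material surrounds the voxel, so air contributes no scatter
#' source, denser and deeper media contribute more.  The yielded activity is
#' convolved with the fitted scatter-source shape kernel and
#' forward-projected with the attenuated projector, giving the main-window
#' scatter estimate.  When the activity estimate comes from an uncorrected
#' reconstruction it still contains the scatter counts, so the result is
#' deflated by `1/(1 + s2p_object)` with the object's own predicted
#' scatter-to-primary ratio (disable via `estimateIncludesScatter = FALSE`).
#'
#' @param activityEstimate activity grid (e.g. an uncorrected OSEM image).
#' @param mu attenuation map, cm^-1, same shape.
#' @param kernels an `esseKernels` fit (at 140 keV).
#' @param geometry an [AcquisitionGeometry-class].
#' @param voxelSize voxel edge, mm.
#' @param estimateIncludesScatter logical, see Details.
#' @return a [ScatterEstimate-class].
#' @export
esseEstimate <- function(activityEstimate, mu, kernels,
                         geometry = acquisitionGeometry(),
                         voxelSize = NULL, estimateIncludesScatter = TRUE) {
  if (is.null(kernels)) stop("missing kernels")
  activityEstimate <- as.matrix(activityEstimate)
  if (!all(dim(activityEstimate) == dim(mu)))
    stop("activity/mu shape mismatch")
  if (any(activityEstimate < 0)) stop("activity estimate must be nonnegative")
  voxelSize <- voxelSize %||% geometry@binSize
  k2 <- esseKernelMatrix(kernels, voxelSize)
  kShape <- k2 / sum(k2)
  scale <- if (is.finite(kernels$s2pScale %||% NA_real_))
    kernels$s2pScale else kernels$s2p
  attnK <- if (is.finite(kernels$attnFwhm %||% NA_real_))
    attnKernelMatrix(kernels$attnFwhm, voxelSize) else kShape
  yield <- scale * conv2same(mu, attnK) / kernels$muRef
  source <- conv2same(activityEstimate * yield, kShape)
  est <- idealForwardProject(source, mu, geometry, voxelSize = voxelSize) /
    geometry@nAngles
  if (estimateIncludesScatter) {
    aTot <- sum(activityEstimate)
    s2pObj <- if (aTot > 0) sum(activityEstimate * yield) / aTot else 0
    est <- est / (1 + s2pObj)
  }
  new("ScatterEstimate", estimate = pmax(est, 0), method = "esse",
      params = list(sigma = kernels$sigma, tau = kernels$tau,
                    beta = kernels$beta, s2p = kernels$s2p),
      clippedBins = 0)
}
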