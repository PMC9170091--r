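# Row-wise Gaussian blur of a sinogram along the detector axis; symmetric
# zero-padded kernel, hence self-transpose (keeps the projector pair matched
# when used on both sides of the EM update).
sinoBlur <- function(sino, fwhmMM, binMM) {
  if (is.null(fwhmMM) || fwhmMM <= 0) return(sino)
  sigma <- fwhmMM / 2.3548200450309493 / binMM
  h <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm((-h):h, 0, sigma)
  k <- k / sum(k)
  out <- sino * 0
  nb <- ncol(sino)
  for (d in (-h):h) {
    src <- seq_len(nb) - d
    ok <- src >= 1 & src <= nb
    out[, ok] <- out[, ok] + k[d + h + 1] * sino[, src[ok], drop = FALSE]
  }
  out
}

#' Attenuated OSEM reconstruction
#'
#' Ordered-subsets expectation maximization with a matched attenuated
#' parallel-beam projector pair (the same discrete model as
#' [idealForwardProject()], normalized by the number of angles so that an
#' interior voxel has unit sensitivity when mu = 0).  Subsets partition the
#' angles by stride; `nSubsets` must divide `nAngles` (15 subsets x 4 angles
#' for the 60-view protocol).  A scatter estimate can enter as an additive
#' term in the forward model, and a stationary Gaussian PSF (resolution
#' recovery) can be applied inside the projector pair.  Voxels never crossed
#' by any ray (zero sensitivity) are masked out.  The default protocol for
#' evaluation runs is 2 iterations x 15 subsets.
#'
#' @param projections main-window count matrix (`nAngles x detectorBins`).
#' @param mu attenuation map, cm^-1, on the reconstruction grid.
#' @param geometry an [AcquisitionGeometry-class].
#' @param nIterations full iterations.
#' @param nSubsets ordered subsets (must divide the number of angles).
#' @param scatterAdditive optional [ScatterEstimate-class] or matrix added
#'   to the forward model (counts).
#' @param psfFwhm optional stationary PSF FWHM, mm (NULL = off).
#' @param voxelSize voxel edge, mm (defaults to the detector bin size).
#' @param initial optional initial image (default uniform positive).
#' @param stepFrac ray-marching step fraction for the attenuation factors.
#' @return a [ReconImage-class]; `reconMeta()` records the protocol.
#' @examples
#' geo <- acquisitionGeometry(nAngles = 12, detectorBins = 24, binSize = 6)
#' truth <- matrix(0, 16, 16); truth[8, 8] <- 100
#' y <- idealForwardProject(truth, geometry = geo, voxelSize = 6) / 12
#' img <- osem(y, matrix(0, 16, 16), geo, nIterations = 10, nSubsets = 1,
#'             voxelSize = 6)
#' @export
osem <- function(projections, mu, geometry = acquisitionGeometry(),
                 nIterations = 2, nSubsets = 15, scatterAdditive = NULL,
                 psfFwhm = NULL, voxelSize = NULL, initial = NULL,
                 stepFrac = 0.25) {
  y <- as.matrix(projections)
  if (any(y < 0)) stop("projections must be nonnegative")
  if (sum(y) <= 0) stop("all-zero projections")
  nAng <- as.integer(geometry@nAngles)
  if (nrow(y) != nAng) stop("projection rows must equal nAngles")
  if (nAng %% nSubsets != 0)
    stop("nSubsets (", nSubsets, ") must divide the number of angles (",
         nAng, ")")
  n <- nrow(mu)
  voxelSize <- voxelSize %||% geometry@binSize
  scat <- if (is(scatterAdditive, "ScatterEstimate"))
    scatterValues(scatterAdditive) else scatterAdditive
  if (!is.null(scat) && !all(dim(scat) == dim(y)))
    stop("scatter term shape mismatch")

  angles <- gantryAngles(geometry)
  attn <- cpp_attenuation_factors(mu / 10, voxelSize, angles, stepFrac)
  nb <- as.integer(geometry@detectorBins)
  scale <- 1 / nAng
  subsets <- lapply(seq_len(nSubsets), function(s)
    seq(s, nAng, by = nSubsets))

  fwd <- function(img, sub) {
    s <- cpp_forward(as.numeric(img), n, voxelSize, angles[sub], sub - 1L,
                     attn, nb, geometry@binSize, scale)
    sinoBlur(s, psfFwhm, geometry@binSize)
  }
  bwd <- function(sino, sub) {
    sino <- sinoBlur(sino, psfFwhm, geometry@binSize)
    matrix(cpp_backward(sino, n, voxelSize, angles[sub], sub - 1L, attn,
                        geometry@binSize, scale), n, n)
  }

  sens <- lapply(subsets, function(sub)
    bwd(matrix(1, length(sub), nb), sub))
  lambda <- if (is.null(initial)) matrix(1, n, n) else as.matrix(initial)
  mask <- Reduce(`+`, sens) > 0
  lambda[!mask] <- 0

  for (it in seq_len(nIterations)) {
    for (s in seq_len(nSubsets)) {
      sub <- subsets[[s]]
      yhat <- fwd(lambda, sub)
      if (!is.null(scat)) yhat <- yhat + scat[sub, , drop = FALSE]
      ratio <- y[sub, , drop = FALSE]
      ratio <- ifelse(yhat > 0, ratio / yhat, 0)
      corr <- bwd(ratio, sub)
      upd <- mask & sens[[s]] > 0
      lambda[upd] <- lambda[upd] * corr[upd] / sens[[s]][upd]
    }
  }
  new("ReconImage", values = pmax(lambda, 0), voxelSize = voxelSize,
      meta = list(iterations = nIterations, subsets = nSubsets,
                  psf_fwhm = psfFwhm,
                  scatter_model = if (is.null(scat)) "none" else "additive",
                  calibration_factor = 1))
}

#' Scalar calibration to activity concentration
#'
#' A single cross-calibration scalar: the known uniform concentration of a
#' reference phantom divided by the mean reconstructed ROI value.  The 2D
#' slice is assigned a thickness of one voxel for the mL conversion.
#'
#' @param image a [ReconImage-class] reconstructed from the reference
#'   phantom.
#' @param referencePhantom the uniform [Phantom-class] with known activity.
#' @param roi a [CircularROI-class] inside the uniform region.
#' @return calibration factor, Bq/mL per reconstructed unit.
#' @export
calibrate <- function(image, referencePhantom, roi) {
  inside <- phantomActivity(referencePhantom) > 0
  volML <- sum(inside) * referencePhantom@voxelSize^3 / 1000
  trueConc <- sum(phantomActivity(referencePhantom)) / volML
  m <- mean(roiPixels(image, roi))
  if (m <= 0) stop("zero mean ROI value")
  trueConc / m
}
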