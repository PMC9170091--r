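#' Sample Compton scattering angles and energies
#'
#' Draws polar scattering angles from the Klein-Nishina differential
#' cross-section at photon energy `E` (the polar density is proportional to
#' the cross-section times `sin(theta)` when integrated over azimuth; the
#' sampler draws `cos(theta)` by rejection) and applies the Compton energy
#' shift `E' = E / (1 + (E/511)(1 - cos(theta)))`.  Uses the current R RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param n number of samples.
#' @param E incident photon energy, keV.
#' @return data.frame with columns `energy` (keV) and `theta` (radians).
#' @examples
#' set.seed(1)
#' s <- sampleCompton(5, 140)
#' all(s$energy <= 140)
#' @export
sampleCompton <- function(n, E = 140) {
  if (E <= 0) stop("E must be positive")
  as.data.frame(cpp_sample_compton(as.integer(n), E))
}

#' Compton-shifted energy (closed form)
#'
#' @param E incident energy, keV.
#' @param theta scattering angle, radians.
#' @return scattered photon energy, keV.
#' @export
comptonEnergy <- function(E, theta) E / (1 + (E / 511) * (1 - cos(theta)))

#' Detector energy resolution model
#'
#' Gaussian blur with `FWHM(E) = r140 * 140 * sqrt(140 / E)` keV, the usual
#' 1/sqrt(E) scaling anchored at a fractional resolution `r140` (default
#' 9.8% FWHM) at 140 keV.  Uses the current R RNG stream.
#'
#' @param E true photon energies, keV.
#' @param r140 fractional FWHM at 140 keV.
#' @return blurred (detected) energies, keV.
#' @export
applyEnergyResolution <- function(E, r140 = 0.098) {
  if (any(E <= 0)) stop("E must be positive")
  fwhm <- r140 * 140 * sqrt(140 / E)
  E + stats::rnorm(length(E), 0, fwhm / 2.3548200450309493)
}

#' Simulate multi-window SPECT projections of a phantom
#'
#' Seeded analogue Monte-Carlo emulation of the acquisition: photons are
#' emitted isotropically from activity-weighted voxels, transported through
#' the attenuation grid (Woodcock tracking; Compton interactions redirect
#' via Klein-Nishina sampling, photoelectric interactions absorb), accepted
#' onto the parallel-beam detector when their exit direction lies within
#' `acceptDeg` of the nearest gantry angle's detector normal, energy-blurred
#' and binned into every window containing the detected energy.  Counts are
#' raw Monte-Carlo tallies (Poisson by construction); absolute sensitivity
#' calibration is a downstream scalar.  Transport is 2D in the slice plane;
#' photons scattered more than `maxOrder` times are discarded.
#'
#' @param phantom a [Phantom-class].
#' @param windows list of [EnergyWindow-class]; must contain one labeled
#'   `"main"`.
#' @param geometry an [AcquisitionGeometry-class].
#' @param histories number of photon histories (>= 1).
#' @param maxOrder maximum Compton scatter order transported (0 = primaries
#'   only).
#' @param seed integer RNG seed; identical inputs give bit-identical output.
#' @param r140 detector fractional FWHM at 140 keV.
#' @param acceptDeg angular half-acceptance of the parallel-hole collimator
#'   model, degrees.
#' @param E0 emission energy, keV.
#' @param eMin transport cutoff energy, keV (photons below are absorbed).
#' @return a [WindowedProjections-class].
#' @examples
#' p <- buildTLSP("water", gridSize = 33, voxelSize = 9.6)
#' wp <- simulateProjections(p, histories = 2e4, seed = 7,
#'                           geometry = acquisitionGeometry(detectorBins = 64,
#'                                                          binSize = 4.8))
#' sum(windowCounts(wp, "main")) == sum(truePrimary(wp)) + sum(trueScatter(wp))
#' @export
simulateProjections <- function(phantom, windows = defaultWindowSet(),
                                geometry = acquisitionGeometry(),
                                histories = 1e6, maxOrder = 3, seed = 1,
                                r140 = 0.098, acceptDeg = 1.5, E0 = 140,
                                eMin = 40) {
  if (histories < 1) stop("histories must be >= 1")
  if (maxOrder < 0) stop("maxOrder must be >= 0")
  if (length(windows) == 0) stop("empty window list")
  labels <- vapply(windows, function(w) w@label, "")
  names(windows) <- labels
  mainIdx <- match("main", labels)
  if (is.na(mainIdx)) stop("windows must include one labeled 'main'")
  if (sum(phantom@activity) <= 0) stop("phantom has zero total activity")

  set.seed(as.integer(seed))
  specBin <- 0.5
  specMax <- 250
  res <- cpp_simulate(phantom@activity, phantom@mu / 10,
                      comptonFractionMap(phantom), phantom@voxelSize,
                      as.integer(geometry@nAngles), geometry@arc,
                      as.integer(geometry@detectorBins), geometry@binSize,
                      vapply(windows, function(w) w@lower, 0),
                      vapply(windows, function(w) w@upper, 0),
                      mainIdx - 1L, as.integer(histories),
                      as.integer(maxOrder), r140, acceptDeg, E0, eMin,
                      specBin, specMax)
  counts <- res$counts
  names(counts) <- labels
  new("WindowedProjections", counts = counts, truePrimary = res$primary,
      trueScatter = res$scatter, spectrum = as.numeric(res$spectrum),
      spectrumBreaks = seq(0, specMax, by = specBin), geometry = geometry,
      windows = windows, seed = seed, histories = histories)
}

#' Noise-free attenuated forward projection
#'
#' Expected primary counts per (angle, bin): attenuated parallel-beam line
#' integrals of the activity grid, with survival factors
#' `exp(-integral of mu)` traced from each voxel to the detector.  A point
#' source of activity `A` in a uniform medium yields `A * exp(-mu R)` per
#' view.  This is the system model used by [osem()] (up to a 1/n_angles
#' sensitivity normalization) and by [esseEstimate()].
#'
#' @param activity activity grid (matrix), or a [Phantom-class].
#' @param mu attenuation grid, cm^-1 (ignored when `activity` is a Phantom).
#' @param geometry an [AcquisitionGeometry-class].
#' @param stepFrac ray-marching step as a fraction of the voxel size.
#' @param voxelSize voxel edge, mm (defaults to the detector bin size when
#'   `activity` is a bare matrix).
#' @return matrix of expected counts, `nAngles x detectorBins`.
#' @export
idealForwardProject <- function(activity, mu = NULL,
                                geometry = acquisitionGeometry(),
                                stepFrac = 0.25, voxelSize = NULL) {
  if (is(activity, "Phantom")) {
    mu <- activity@mu
    voxel <- activity@voxelSize
    activity <- activity@activity
  } else {
    voxel <- if (is.null(voxelSize)) geometry@binSize else voxelSize
  }
  if (is.null(mu)) mu <- matrix(0, nrow(activity), ncol(activity))
  if (!all(dim(activity) == dim(mu))) stop("activity/mu shape mismatch")
  angles <- gantryAngles(geometry)
  attn <- cpp_attenuation_factors(mu / 10, voxel, angles, stepFrac)
  cpp_forward(as.numeric(activity), nrow(activity), voxel, angles,
              seq_along(angles) - 1L, attn,
              as.integer(geometry@detectorBins), geometry@binSize, 1.0)
}
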