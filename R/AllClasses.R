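#' @import methods
NULL

#' Energy acceptance window
#'
#' A labeled `[lower, upper)` keV interval.  Window width is defined as a
#' fraction of the 140 keV Tc-99m reference energy (e.g. `fraction = 0.20`
#' for the +/-10% photopeak window, `0.05` for a 5% sub-window), so
#' `upper - lower == fraction * eRef` always holds.  Windows may overlap:
#' the emulated camera records up to 16 windows simultaneously.
#'
#' @slot label window name, e.g. `"main"`, `"dew20"`, `"tew5_lower"`.
#' @slot center window center, keV.
#' @slot fraction fractional width relative to `eRef`.
#' @slot lower,upper window bounds, keV.
#' @slot eRef reference energy for the fractional width, keV (140).
#' @seealso [energyWindow()], [defaultWindowSet()]
#' @export
setClass("EnergyWindow",
  representation(label = "character", center = "numeric",
                 fraction = "numeric", lower = "numeric", upper = "numeric",
                 eRef = "numeric"))

setValidity("EnergyWindow", function(object) {
  if (object@lower >= object@upper) return("lower must be < upper")
  if (abs((object@upper - object@lower) - object@fraction * object@eRef) > 1e-9)
    return("width must equal fraction * eRef")
  TRUE
})

#' Voxelized digital phantom
#'
#' Activity (Bq per voxel), linear attenuation at 140 keV (cm^-1) and a
#' material-index grid on a common square single-slice grid.  The phantom
#' center sits at the grid center (between voxels for even grids); physical
#' coordinates are voxel-center based.
#'
#' @slot activity numeric matrix, Bq per voxel.
#' @slot mu numeric matrix, linear attenuation coefficient at 140 keV, cm^-1.
#' @slot labels integer matrix of row indices into `materials`.
#' @slot voxelSize voxel edge length, mm.
#' @slot name phantom name.
#' @slot materials data.frame as returned by [materialTable()].
#' @seealso [buildTLSP()], [buildUniformCylinder()]
#' @export
setClass("Phantom",
  representation(activity = "matrix", mu = "matrix", labels = "matrix",
                 voxelSize = "numeric", name = "character",
                 materials = "data.frame"))

setValidity("Phantom", function(object) {
  if (!all(dim(object@activity) == dim(object@mu)) ||
      !all(dim(object@activity) == dim(object@labels)))
    return("activity, mu and labels must share one shape")
  if (any(object@activity < 0)) return("activity must be nonnegative")
  if (any(object@mu < 0)) return("mu must be nonnegative")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  TRUE
})

#' Acquisition geometry
#'
#' Parallel-beam step-and-shoot orbit: 60 views of 20 s over 360 degrees
#' onto a 128-bin detector row with 4.8 mm bins by default.
#'
#' @slot nAngles number of projection angles.
#' @slot arc orbit arc, degrees.
#' @slot detectorBins detector bins per view.
#' @slot binSize detector bin width, mm.
#' @slot timePerView acquisition time per view, s.
#' @seealso [acquisitionGeometry()]
#' @export
setClass("AcquisitionGeometry",
  representation(nAngles = "numeric", arc = "numeric",
                 detectorBins = "numeric", binSize = "numeric",
                 timePerView = "numeric"))

setValidity("AcquisitionGeometry", function(object) {
  if (object@nAngles < 1) return("nAngles must be >= 1")
  if (object@binSize <= 0) return("binSize must be positive")
  if (object@arc <= 0) return("arc must be positive")
  TRUE
})

#' Multi-window projection data
#'
#' Per-window count sinograms over (angle, bin), plus the simulation-only
#' ground truth: the main-window split into unscattered (`truePrimary`) and
#' scattered (`trueScatter`) counts, where a photon is scattered iff it
#' underwent at least one Compton interaction before detection.  For the
#' main window `counts == truePrimary + trueScatter` exactly.
#'
#' @slot counts named list of count matrices, one per window.
#' @slot truePrimary,trueScatter main-window ground-truth matrices.
#' @slot spectrum detected-photon energy histogram (all detected photons).
#' @slot spectrumBreaks histogram bin breaks, keV.
#' @slot geometry an [AcquisitionGeometry-class].
#' @slot windows list of [EnergyWindow-class] objects.
#' @slot seed RNG seed used for the simulation.
#' @slot histories number of photon histories.
#' @seealso [simulateProjections()]
#' @export
setClass("WindowedProjections",
  representation(counts = "list", truePrimary = "matrix",
                 trueScatter = "matrix", spectrum = "numeric",
                 spectrumBreaks = "numeric", geometry = "AcquisitionGeometry",
                 windows = "list", seed = "numeric", histories = "numeric"))

setValidity("WindowedProjections", function(object) {
  for (m in object@counts) {
    if (any(m < 0)) return("counts must be nonnegative")
    if (any(m != round(m))) return("counts must be integer-valued")
  }
  if (!"main" %in% names(object@counts)) return("a 'main' window is required")
  main <- object@counts[["main"]]
  if (max(abs(main - (object@truePrimary + object@trueScatter))) > 0)
    return("main counts must equal truePrimary + trueScatter")
  TRUE
})

#' Projection-space scatter estimate
#'
#' Estimated scattered counts inside the main window per (angle, bin), as
#' produced by [dewEstimate()], [tewEstimate()], [esseEstimate()] or the
#' simulator ground truth.
#'
#' @slot estimate nonnegative matrix of estimated scattered counts.
#' @slot method method label (`"dew"`, `"tew"`, `"esse"`, `"truth"`, `"none"`).
#' @slot params method parameters (e.g. `k`, sub-window fraction).
#' @slot clippedBins number of bins clipped at zero by [applyCorrection()].
#' @export
setClass("ScatterEstimate",
  representation(estimate = "matrix", method = "character", params = "list",
                 clippedBins = "numeric"))

setValidity("ScatterEstimate", function(object) {
  if (any(object@estimate < 0)) return("estimate must be nonnegative")
  TRUE
})

#' Reconstructed image
#'
#' Output of [osem()]: nonnegative voxel values on the phantom grid, with
#' the protocol (iterations, subsets, corrections, calibration factor)
#' recorded in `meta`.
#'
#' @slot values nonnegative matrix of reconstructed values.
#' @slot voxelSize voxel edge length, mm.
#' @slot meta list describing iterations, subsets and corrections applied.
#' @export
setClass("ReconImage",
  representation(values = "matrix", voxelSize = "numeric", meta = "list"))

setValidity("ReconImage", function(object) {
  if (any(object@values < 0)) return("values must be nonnegative (EM)")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  TRUE
})

#' Circular region of interest
#'
#' @slot centerMM ROI center in mm relative to the grid center.
#' @slot diameterMM ROI diameter, mm.
#' @slot slices number of slices (noise realizations in 2D mode) averaged.
#' @seealso [circularROI()], [roiCounts()]
#' @export
setClass("CircularROI",
  representation(centerMM = "numeric", diameterMM = "numeric",
                 slices = "numeric"))

setValidity("CircularROI", function(object) {
  if (object@diameterMM <= 0) return("diameterMM must be positive")
  if (length(object@centerMM) != 2) return("centerMM must have length 2")
  TRUE
})
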