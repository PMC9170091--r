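#' Dual-energy-window (DEW) scatter estimate
#'
#' The Compton sub-window counts, scaled by the scatter multiplier `k`, are
#' taken as the estimate of scattered counts inside the photopeak window:
#' `Cprim = Ctotal - k * Cs` with `k = 1` for Tc-99m by default.
#'
#' @param subCounts Compton sub-window counts per (angle, bin).
#' @param k scatter multiplier (> 0).
#' @param subFraction sub-window fractional width, recorded in the params.
#' @return a [ScatterEstimate-class] with `estimate = k * subCounts`.
#' @examples
#' scatterValues(dewEstimate(matrix(30), k = 1))   # 30
#' @export
dewEstimate <- function(subCounts, k = 1, subFraction = NA_real_) {
  subCounts <- as.matrix(subCounts)
  if (any(subCounts < 0)) stop("negative input counts")
  if (k <= 0) stop("k must be positive")
  new("ScatterEstimate", estimate = k * subCounts, method = "dew",
      params = list(k = k, sub_fraction = subFraction), clippedBins = 0)
}

#' Effective TEW scatter multiplier
#'
#' The trapezoid estimate of photopeak scatter from two flanking sub-windows
#' is `(Clower + Chigher)/2 * Wprim/Wsub`; folding the 1/2 into the
#' multiplier gives `k_eff = Wprim / (2 Wsub) = mainFraction /
#' (2 subFraction)`, the tabulated value (3% -> 3.3, 5% -> 2.0, 7% -> 1.4,
#' 10% -> 1.0 for a +/-10% main window, at one decimal).
#'
#' @param mainFraction photopeak fractional width (0.20 for +/-10%).
#' @param subFraction sub-window fractional width.
#' @param eRef reference energy, keV (cancels; kept for clarity of units).
#' @return the dimensionless multiplier `k_eff`.
#' @examples
#' round(tewK(0.20, 0.05), 1)   # 2.0
#' @export
tewK <- function(mainFraction, subFraction, eRef = 140) {
  if (mainFraction <= 0 || subFraction <= 0)
    stop("window fractions must be positive")
  (mainFraction * eRef) / (2 * subFraction * eRef)
}

#' Triple-energy-window (TEW) scatter estimate
#'
#' Trapezoidal estimate of the scatter inside the photopeak window from the
#' two narrow flanking sub-windows:
#' `estimate = kLower * Clower + kHigher * Chigher`, where the multipliers
#' already contain the trapezoid 1/2 (see [tewK()]).  Exact for any scatter
#' spectrum linear across the three windows.
#'
#' @param lowerCounts,higherCounts sub-window counts per (angle, bin).
#' @param kLower,kHigher multipliers, typically both [tewK()].
#' @param subFraction sub-window fractional width, recorded in the params.
#' @return a [ScatterEstimate-class].
#' @export
tewEstimate <- function(lowerCounts, higherCounts, kLower, kHigher = kLower,
                        subFraction = NA_real_) {
  lowerCounts <- as.matrix(lowerCounts)
  higherCounts <- as.matrix(higherCounts)
  if (!all(dim(lowerCounts) == dim(higherCounts)))
    stop("shape mismatch between sub-window counts")
  if (any(lowerCounts < 0) || any(higherCounts < 0))
    stop("negative input counts")
  new("ScatterEstimate",
      estimate = kLower * lowerCounts + kHigher * higherCounts,
      method = "tew",
      params = list(k_lower = kLower, k_higher = kHigher,
                    sub_fraction = subFraction),
      clippedBins = 0)
}

#' Apply a scatter estimate to the photopeak data
#'
#' Two modes, because vendors differ in where the estimate enters:
#' `"subtract_clip"` subtracts the estimate from the photopeak counts in
#' projection space and clips negative bins at zero (clipped bins counted,
#' so over-correction is quantifiable); `"additive_model"` leaves the data
#' untouched and forwards the estimate to [osem()] as an additive term in
#' the forward model.
#'
#' @param projections a [WindowedProjections-class] or a main-window count
#'   matrix.
#' @param estimate a [ScatterEstimate-class].
#' @param mode `"subtract_clip"` or `"additive_model"`.
#' @return list with `counts` (main-window data to reconstruct),
#'   `scatterAdditive` (matrix for [osem()]'s additive term, or NULL),
#'   `estimate` (the [ScatterEstimate-class], clip count updated) and
#'   `mode`.
#' @examples
#' co <- applyCorrection(matrix(100), dewEstimate(matrix(30)))
#' co$counts   # 70
#' @export
applyCorrection <- function(projections, estimate,
                            mode = c("subtract_clip", "additive_model")) {
  mode <- match.arg(mode)
  counts <- if (is(projections, "WindowedProjections"))
    windowCounts(projections, "main") else as.matrix(projections)
  est <- scatterValues(estimate)
  if (!all(dim(counts) == dim(est)))
    stop("shape mismatch between data and estimate")
  if (mode == "subtract_clip") {
    corrected <- counts - est
    nClip <- sum(corrected < 0)
    corrected[corrected < 0] <- 0
    estimate@clippedBins <- estimate@clippedBins + nClip
    list(counts = corrected, scatterAdditive = NULL, estimate = estimate,
         mode = mode)
  } else {
    list(counts = counts, scatterAdditive = est, estimate = estimate,
         mode = mode)
  }
}

#' Projection-space scatter estimate for a named correction method
#'
#' Dispatcher used by the experiment matrix.  Method strings: `"none"`,
#' `"truth"` (simulator ground truth), `"dew5"`/`"dew10"`/`"dew15"`/
#' `"dew20"` (Compton sub-window percent, k = 1), `"tew3"`/`"tew5"`/
#' `"tew7"`/`"tew10"` (flanking sub-window percent, k from [tewK()]), or
#' `"esse"` (requires `kernels` and the attenuation map; the activity
#' estimate defaults to an uncorrected OSEM reconstruction).
#'
#' @param wp a [WindowedProjections-class] simulated with
#'   [defaultWindowSet()] labels.
#' @param method method string.
#' @param k DEW scatter multiplier.
#' @param kernels ESSE kernel set from [esseFitKernels()].
#' @param mu attenuation map (cm^-1) for ESSE.
#' @param activityEstimate optional activity grid for ESSE.
#' @param voxelSize voxel size of the activity grid, mm.
#' @return a [ScatterEstimate-class].
#' @export
estimateScatter <- function(wp, method, k = 1, kernels = NULL, mu = NULL,
                            activityEstimate = NULL, voxelSize = NULL) {
  stopifnot(is(wp, "WindowedProjections"))
  main <- windowCounts(wp, "main")
  if (method == "none")
    return(new("ScatterEstimate", estimate = main * 0, method = "none",
               params = list(), clippedBins = 0))
  if (method == "truth")
    return(new("ScatterEstimate", estimate = trueScatter(wp),
               method = "truth", params = list(), clippedBins = 0))
  if (grepl("^dew[0-9]+$", method)) {
    f <- as.numeric(sub("dew", "", method)) / 100
    return(dewEstimate(windowCounts(wp, method), k = k, subFraction = f))
  }
  if (grepl("^tew[0-9]+$", method)) {
    f <- as.numeric(sub("tew", "", method)) / 100
    mainFrac <- wp@windows[["main"]]@fraction
    ke <- tewK(mainFrac, f)
    return(tewEstimate(windowCounts(wp, paste0(method, "_lower")),
                       windowCounts(wp, paste0(method, "_upper")),
                       kLower = ke, kHigher = ke, subFraction = f))
  }
  if (method == "esse") {
    if (is.null(kernels) || is.null(mu)) stop("esse requires kernels and mu")
    if (is.null(activityEstimate)) {
      geo <- acqGeometry(wp)
      nsub <- if (geo@nAngles %% 15 == 0) 15 else 1
      rec <- osem(main, mu, geo, nIterations = 2, nSubsets = nsub,
                  voxelSize = voxelSize)
      activityEstimate <- reconValues(rec)
      voxelSize <- voxelSize %||% rec@voxelSize
    }
    return(esseEstimate(activityEstimate, mu, kernels, acqGeometry(wp),
                        voxelSize = voxelSize))
  }
  stop("unknown correction method '", method, "'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
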