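#' Construct a circular ROI
#'
#' @param diameterMM ROI diameter, mm.
#' @param centerMM ROI center in mm relative to the grid center.
#' @param slices number of slices (2D mode: independent noise realizations)
#'   the ROI statistic is averaged over.
#' @return a [CircularROI-class].
#' @export
circularROI <- function(diameterMM, centerMM = c(0, 0), slices = 10) {
  new("CircularROI", centerMM = centerMM, diameterMM = diameterMM,
      slices = slices)
}

roiMask <- function(image, roi) {
  vals <- if (is(image, "ReconImage")) reconValues(image) else as.matrix(image)
  v <- if (is(image, "ReconImage")) voxelSize(image) else
    attr(image, "voxelSize") %||% 1
  n <- nrow(vals)
  half <- n * v / 2
  if (any(abs(roi@centerMM) + roi@diameterMM / 2 > half))
    stop("ROI extends outside the image")
  list(values = vals, mask = circleMask(n, v, roi@diameterMM, roi@centerMM))
}

#' ROI pixel values
#'
#' @param image a [ReconImage-class] or matrix (matrix input takes its mm
#'   scale from a `voxelSize` attribute, else 1 mm voxels).
#' @param roi a [CircularROI-class].
#' @return numeric vector of the pixel values inside the circle.
#' @export
roiPixels <- function(image, roi) {
  rm <- roiMask(image, roi)
  rm$values[rm$mask]
}

#' ROI counts (mean of slice sums)
#'
#' Sum of all pixel values inside the circle per slice, averaged over
#' slices.  In the 2D single-slice mode, a list of images is treated as
#' independent noise realizations standing in for the slices.
#'
#' @param image a [ReconImage-class], matrix, or list of them.
#' @param roi a [CircularROI-class].
#' @return mean-of-slice-sums, counts.
#' @export
roiCounts <- function(image, roi) {
  if (is.list(image) && !is(image, "ReconImage"))
    return(mean(vapply(image, function(im) sum(roiPixels(im, roi)), 0)))
  sum(roiPixels(image, roi))
}

#' Scatter fraction
#'
#' Relative excess of medium-background ROI counts over the air-background
#' reference: `SF% = (T_medium - T_air) / T_medium * 100`.  Negative values
#' report over-correction below the air reference.
#'
#' @param tMedium ROI counts for the water or bone-equivalent background.
#' @param tAir ROI counts for the air background (reference).
#' @return SF, percent.
#' @examples
#' scatterFraction(120, 100)   # 16.67
#' @export
scatterFraction <- function(tMedium, tAir) {
  if (tMedium == 0) stop("tMedium must be nonzero")
  (tMedium - tAir) / tMedium * 100
}

#' Normalized mean-square error
#'
#' `NMSE% = sum((air - medium)^2) / sum(air^2) * 100` over all ROI pixels
#' (and slices).
#'
#' @param airValues ROI pixel values of the air-background reference.
#' @param mediumValues ROI pixel values of the medium background.
#' @return NMSE, percent.
#' @examples
#' nmse(rep(100, 9), rep(110, 9))   # 1
#' @export
nmse <- function(airValues, mediumValues) {
  if (length(airValues) != length(mediumValues)) stop("shape mismatch")
  den <- sum(airValues^2)
  if (den == 0) stop("air reference is all zero")
  sum((airValues - mediumValues)^2) / den * 100
}

#' Coefficient of variation
#'
#' `CV% = SD / mean * 100` of the pixel values in a central circular ROI of
#' the uniform phantom (an image-uniformity / noise index).  SD uses the
#' population convention (divide by N); the convention is recorded in the
#' attribute `sd_convention`.
#'
#' @param image a [ReconImage-class] or matrix.
#' @param roi a [CircularROI-class].
#' @return CV, percent.
#' @export
cv <- function(image, roi) {
  px <- roiPixels(image, roi)
  m <- mean(px)
  if (m <= 0) stop("zero mean in ROI")
  sdPop <- sqrt(mean((px - m)^2))
  structure(sdPop / m * 100, sd_convention = "population")
}

#' Residual-scatter difference image
#'
#' Elementwise `image - reference`, the residual-scatter visualization:
#' positive residual marks scattered radiation left uncorrected relative to
#' the reference correction (DEW 20% in the evaluation design).
#'
#' @param image,reference [ReconImage-class] objects on the same grid.
#' @return numeric matrix of differences.
#' @export
residualImage <- function(image, reference) {
  a <- if (is(image, "ReconImage")) reconValues(image) else as.matrix(image)
  b <- if (is(reference, "ReconImage")) reconValues(reference) else
    as.matrix(reference)
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (is(image, "ReconImage") && is(reference, "ReconImage") &&
      abs(voxelSize(image) - voxelSize(reference)) > 1e-9)
    stop("voxel size mismatch")
  a - b
}
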