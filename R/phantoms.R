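#' Material catalogue
#'
#' The three media used by the phantom study: air, water and a
#' bone-equivalent dipotassium hydrogen phosphate (K2HPO4) solution.  Linear
#' attenuation coefficients are at 140 keV.  The water default (0.151 cm^-1)
#' sits within 2% of the narrow-beam tabulated value at 140 keV; the
#' K2HPO4 concentration of the physical solution is not fixed, so its mu is
#' a free parameter defaulted near a cortical-bone-like value.
#' `compton_fraction` is the fraction of interactions at 140 keV that are
#' Compton rather than photoelectric.
#'
#' @param muAir,muWater,muK2HPO4 linear attenuation at 140 keV, cm^-1.
#' @param comptonAir,comptonWater,comptonK2HPO4 Compton interaction fractions.
#' @return data.frame with columns `name`, `mu_140`, `density`,
#'   `compton_fraction`; one row per material, air first.
#' @examples
#' materialTable()
#' @export
materialTable <- function(muAir = 2e-4, muWater = 0.151, muK2HPO4 = 0.25,
                          comptonAir = 1.0, comptonWater = 0.999,
                          comptonK2HPO4 = 0.97) {
  data.frame(
    name = c("air", "water", "k2hpo4"),
    mu_140 = c(muAir, muWater, muK2HPO4),
    density = c(0.0012, 1.00, 1.33),
    compton_fraction = c(comptonAir, comptonWater, comptonK2HPO4),
    stringsAsFactors = FALSE)
}

# Pixel-center rasterization of a circle; center in mm from grid center.
circleMask <- function(n, voxelSize, diameterMM, centerMM = c(0, 0)) {
  coord <- (seq_len(n) - (n + 1) / 2) * voxelSize
  x <- matrix(coord, n, n, byrow = TRUE) - centerMM[1]
  y <- matrix(coord, n, n) - centerMM[2]
  x^2 + y^2 <= (diameterMM / 2)^2
}

# Index (row = col) of the voxel holding the central line source.
centralIndex <- function(n) floor(n / 2) + 1L

newPhantom <- function(activity, labels, voxelSize, name, materials) {
  mu <- matrix(materials$mu_140[labels], nrow(labels), ncol(labels))
  new("Phantom", activity = activity, mu = mu, labels = labels,
      voxelSize = voxelSize, name = name, materials = materials)
}

#' Triple line source phantom (TLSP), single remaining central line
#'
#' A 20 cm diameter cylinder of the chosen background medium with a ~1 mm
#' line source at the center carrying the whole activity (74.0 MBq of Tc-99m
#' by default).  Because the line is narrower than a voxel, all of its
#' activity is assigned to the single central voxel; outside the cylinder is
#' air.  Single transaxial slice.
#'
#' @param medium background material: `"air"`, `"water"` or `"k2hpo4"`.
#' @param gridSize grid edge, voxels.
#' @param voxelSize voxel edge, mm.
#' @param activity total line-source activity, Bq.
#' @param diameterMM phantom inner diameter, mm.
#' @param materials material catalogue, see [materialTable()].
#' @return a [Phantom-class].
#' @examples
#' p <- buildTLSP("water", gridSize = 65, voxelSize = 4.8)
#' sum(phantomActivity(p)) / 1e6   # 74 MBq
#' @export
buildTLSP <- function(medium = c("water", "air", "k2hpo4"), gridSize = 128,
                      voxelSize = 4.8, activity = 74e6, diameterMM = 200,
                      materials = materialTable()) {
  medium <- match.arg(medium)
  if (voxelSize <= 0) stop("voxelSize must be positive")
  if (gridSize * voxelSize < diameterMM)
    stop("grid too small to contain the ", diameterMM, " mm phantom")
  n <- as.integer(gridSize)
  mIdx <- match(medium, materials$name)
  labels <- matrix(match("air", materials$name), n, n)
  labels[circleMask(n, voxelSize, diameterMM)] <- mIdx
  act <- matrix(0, n, n)
  ci <- centralIndex(n)
  act[ci, ci] <- activity
  newPhantom(act, labels, voxelSize, paste0("tlsp_", medium), materials)
}

#' Uniform cylinder phantom
#'
#' A 16 cm diameter cylinder of bone-equivalent K2HPO4 solution with the
#' activity (222.0 MBq of Tc-99m by default) distributed uniformly over the
#' interior voxels.  Single transaxial slice.
#'
#' @inheritParams buildTLSP
#' @param activity total activity, Bq.
#' @param diameterMM cylinder inner diameter, mm.
#' @return a [Phantom-class].
#' @examples
#' u <- buildUniformCylinder(gridSize = 64)
#' sum(phantomActivity(u)) / 1e6   # 222 MBq
#' @export
buildUniformCylinder <- function(gridSize = 128, voxelSize = 4.8,
                                 activity = 222e6, diameterMM = 160,
                                 materials = materialTable()) {
  if (voxelSize <= 0) stop("voxelSize must be positive")
  if (gridSize * voxelSize < diameterMM)
    stop("grid too small to contain the ", diameterMM, " mm phantom")
  n <- as.integer(gridSize)
  inside <- circleMask(n, voxelSize, diameterMM)
  labels <- matrix(match("air", materials$name), n, n)
  labels[inside] <- match("k2hpo4", materials$name)
  act <- matrix(0, n, n)
  act[inside] <- activity / sum(inside)
  newPhantom(act, labels, voxelSize, "uniform_cylinder", materials)
}

# Per-voxel Compton interaction fraction from the material labels.
comptonFractionMap <- function(phantom) {
  matrix(phantom@materials$compton_fraction[phantom@labels],
         nrow(phantom@labels), ncol(phantom@labels))
}
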