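#' Construct an energy window
#'
#' Width is `fraction * eRef` keV, centered on `center`.  The photopeak
#' (main) window is the +/-10% window at 140 keV, i.e.
#' `energyWindow("main", 140, 0.20)` = [126, 154) keV.
#'
#' @param label window name.
#' @param center window center, keV.
#' @param fraction fractional width relative to `eRef`.
#' @param eRef reference energy, keV.
#' @return an [EnergyWindow-class].
#' @export
energyWindow <- function(label, center, fraction, eRef = 140) {
  w <- fraction * eRef
  new("EnergyWindow", label = label, center = center, fraction = fraction,
      lower = center - w / 2, upper = center + w / 2, eRef = eRef)
}

#' @describeIn energyWindow the +/-10% photopeak window at 140 keV.
#' @export
mainWindow <- function(eRef = 140) energyWindow("main", eRef, 0.20, eRef)

#' @describeIn energyWindow a DEW Compton sub-window of the given fractional
#'   width, adjacent below the main window (upper edge at 126 keV).
#' @export
dewSubWindow <- function(fraction, eRef = 140) {
  lowerEdge <- eRef - 0.20 * eRef / 2
  energyWindow(sprintf("dew%g", 100 * fraction),
               lowerEdge - fraction * eRef / 2, fraction, eRef)
}

#' @describeIn energyWindow the pair of TEW sub-windows of the given
#'   fractional width abutting the main window on both sides.
#' @export
tewSubWindows <- function(fraction, eRef = 140) {
  lo <- eRef - 0.20 * eRef / 2
  hi <- eRef + 0.20 * eRef / 2
  list(energyWindow(sprintf("tew%g_lower", 100 * fraction),
                    lo - fraction * eRef / 2, fraction, eRef),
       energyWindow(sprintf("tew%g_upper", 100 * fraction),
                    hi + fraction * eRef / 2, fraction, eRef))
}

#' Default simultaneous window set
#'
#' The photopeak window plus every DEW and TEW sub-window of the evaluated
#' protocol: DEW 5/10/15/20% Compton windows below the photopeak and TEW
#' 3/5/7/10% flanking pairs — 13 windows, within the camera's simultaneous
#' limit of 16.
#'
#' @param dewFractions DEW sub-window fractional widths.
#' @param tewFractions TEW sub-window fractional widths.
#' @param eRef reference energy, keV.
#' @return list of [EnergyWindow-class], main window first.
#' @examples
#' vapply(defaultWindowSet(), function(w) w@label, "")
#' @export
defaultWindowSet <- function(dewFractions = c(0.05, 0.10, 0.15, 0.20),
                             tewFractions = c(0.03, 0.05, 0.07, 0.10),
                             eRef = 140) {
  wins <- list(mainWindow(eRef))
  for (f in dewFractions) wins <- c(wins, dewSubWindow(f, eRef))
  for (f in tewFractions) wins <- c(wins, tewSubWindows(f, eRef))
  names(wins) <- vapply(wins, function(w) w@label, "")
  wins
}

#' Acquisition geometry constructor
#'
#' Defaults mirror the evaluated protocol: 60 views of 20 s over 360 degrees,
#' 128 detector bins of 4.8 mm.
#'
#' @param nAngles number of projection angles.
#' @param arc orbit arc, degrees.
#' @param detectorBins detector bins per view.
#' @param binSize bin width, mm.
#' @param timePerView seconds per view.
#' @return an [AcquisitionGeometry-class].
#' @export
acquisitionGeometry <- function(nAngles = 60, arc = 360, detectorBins = 128,
                                binSize = 4.8, timePerView = 20) {
  new("AcquisitionGeometry", nAngles = nAngles, arc = arc,
      detectorBins = detectorBins, binSize = binSize,
      timePerView = timePerView)
}

gantryAngles <- function(geometry) {
  (seq_len(geometry@nAngles) - 1) * geometry@arc / geometry@nAngles * pi / 180
}
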