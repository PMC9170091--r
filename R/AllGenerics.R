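#' Accessors for spectscatter classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the matching class.
#' @param label window label (for [windowCounts()]).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("phantomActivity", function(x) standardGeneric("phantomActivity"))
#' @rdname accessors
#' @export
setGeneric("attenuationMap", function(x) standardGeneric("attenuationMap"))
#' @rdname accessors
#' @export
setGeneric("materialLabels", function(x) standardGeneric("materialLabels"))
#' @rdname accessors
#' @export
setGeneric("phantomMaterials", function(x) standardGeneric("phantomMaterials"))
#' @rdname accessors
#' @export
setGeneric("windowCounts", function(x, label) standardGeneric("windowCounts"))
#' @rdname accessors
#' @export
setGeneric("truePrimary", function(x) standardGeneric("truePrimary"))
#' @rdname accessors
#' @export
setGeneric("trueScatter", function(x) standardGeneric("trueScatter"))
#' @rdname accessors
#' @export
setGeneric("energyWindows", function(x) standardGeneric("energyWindows"))
#' @rdname accessors
#' @export
setGeneric("acqGeometry", function(x) standardGeneric("acqGeometry"))
#' @rdname accessors
#' @export
setGeneric("scatterValues", function(x) standardGeneric("scatterValues"))
#' @rdname accessors
#' @export
setGeneric("clippedBins", function(x) standardGeneric("clippedBins"))
#' @rdname accessors
#' @export
setGeneric("reconValues", function(x) standardGeneric("reconValues"))
#' @rdname accessors
#' @export
setGeneric("reconMeta", function(x) standardGeneric("reconMeta"))

#' @rdname accessors
#' @export
setMethod("voxelSize", "Phantom", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "ReconImage", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("phantomActivity", "Phantom", function(x) x@activity)
#' @rdname accessors
#' @export
setMethod("attenuationMap", "Phantom", function(x) x@mu)
#' @rdname accessors
#' @export
setMethod("materialLabels", "Phantom", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("phantomMaterials", "Phantom", function(x) x@materials)
#' @rdname accessors
#' @export
setMethod("windowCounts", "WindowedProjections", function(x, label) {
  if (!label %in% names(x@counts))
    stop("no window labeled '", label, "' (have: ",
         paste(names(x@counts), collapse = ", "), ")")
  x@counts[[label]]
})
#' @rdname accessors
#' @export
setMethod("truePrimary", "WindowedProjections", function(x) x@truePrimary)
#' @rdname accessors
#' @export
setMethod("trueScatter", "WindowedProjections", function(x) x@trueScatter)
#' @rdname accessors
#' @export
setMethod("energyWindows", "WindowedProjections", function(x) x@windows)
#' @rdname accessors
#' @export
setMethod("acqGeometry", "WindowedProjections", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("scatterValues", "ScatterEstimate", function(x) x@estimate)
#' @rdname accessors
#' @export
setMethod("clippedBins", "ScatterEstimate", function(x) x@clippedBins)
#' @rdname accessors
#' @export
setMethod("reconValues", "ReconImage", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("reconMeta", "ReconImage", function(x) x@meta)

setMethod("show", "EnergyWindow", function(object) {
  cat(sprintf("EnergyWindow '%s': [%.1f, %.1f) keV (%.0f%% of %g keV)\n",
              object@label, object@lower, object@upper,
              100 * object@fraction, object@eRef))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@activity)
  cat(sprintf("Phantom '%s': %dx%d grid @ %.1f mm, total activity %.3g MBq\n",
              object@name, d[1], d[2], object@voxelSize,
              sum(object@activity) / 1e6))
  cat("  materials:", paste(object@materials$name, collapse = ", "), "\n")
})

setMethod("show", "AcquisitionGeometry", function(object) {
  cat(sprintf(
    "AcquisitionGeometry: %d views x %g s over %g deg, %d bins @ %.1f mm\n",
    object@nAngles, object@timePerView, object@arc, object@detectorBins,
    object@binSize))
})

setMethod("show", "WindowedProjections", function(object) {
  main <- object@counts[["main"]]
  cat(sprintf(
    "WindowedProjections: %d windows, %d x %d sinograms, %g histories (seed %g)\n",
    length(object@counts), nrow(main), ncol(main), object@histories,
    object@seed))
  sf <- sum(object@trueScatter) / max(1, sum(main))
  cat(sprintf("  main-window counts %g (true scatter-to-total %.3f)\n",
              sum(main), sf))
})

setMethod("show", "ScatterEstimate", function(object) {
  cat(sprintf("ScatterEstimate [%s]: total %.4g counts, %d clipped bins\n",
              object@method, sum(object@estimate), object@clippedBins))
})

setMethod("show", "ReconImage", function(object) {
  d <- dim(object@values)
  it <- object@meta$iterations; su <- object@meta$subsets
  cat(sprintf("ReconImage: %dx%d @ %.1f mm, OSEM %s it x %s subsets\n",
              d[1], d[2], object@voxelSize,
              ifelse(is.null(it), "?", it), ifelse(is.null(su), "?", su)))
})

setMethod("show", "CircularROI", function(object) {
  cat(sprintf("CircularROI: %.1f mm diameter at (%.1f, %.1f) mm, %d slices\n",
              object@diameterMM, object@centerMM[1], object@centerMM[2],
              object@slices))
})
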