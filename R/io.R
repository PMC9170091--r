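# NIfTI + JSON-sidecar serialization.  Activity and attenuation go out as
# separate volumes; windows, geometry, seed and histories live in the
# sidecar so a projection set is self-describing.

windowsToDF <- function(windows) {
  do.call(rbind, lapply(windows, function(w)
    data.frame(label = w@label, center = w@center, fraction = w@fraction,
               lower = w@lower, upper = w@upper, eRef = w@eRef,
               stringsAsFactors = FALSE)))
}

dfToWindows <- function(df) {
  wins <- lapply(seq_len(nrow(df)), function(i)
    new("EnergyWindow", label = df$label[i], center = df$center[i],
        fraction = df$fraction[i], lower = df$lower[i], upper = df$upper[i],
        eRef = df$eRef[i]))
  names(wins) <- df$label
  wins
}

writeNiftiGrid <- function(m, path, voxelSize) {
  img <- RNifti::asNifti(array(m, dim = c(dim(m), 1)),
                         pixdim = c(voxelSize, voxelSize, voxelSize))
  RNifti::writeNifti(img, path)
}

readNiftiGrid <- function(path) {
  a <- RNifti::readNifti(path)
  matrix(as.numeric(a), dim(a)[1], dim(a)[2])
}

#' Write / read a phantom as NIfTI volumes with a JSON sidecar
#'
#' `<prefix>_activity.nii.gz`, `<prefix>_mu.nii.gz`, `<prefix>_labels.nii.gz`
#' and `<prefix>.json` (name, materials, voxel size, total activity).
#'
#' @param phantom a [Phantom-class].
#' @param prefix output path prefix.
#' @return `writePhantom`: invisibly, the sidecar path.  `readPhantom`: the
#'   [Phantom-class].
#' @export
writePhantom <- function(phantom, prefix) {
  writeNiftiGrid(phantom@activity, paste0(prefix, "_activity.nii.gz"),
                 phantom@voxelSize)
  writeNiftiGrid(phantom@mu, paste0(prefix, "_mu.nii.gz"), phantom@voxelSize)
  writeNiftiGrid(phantom@labels, paste0(prefix, "_labels.nii.gz"),
                 phantom@voxelSize)
  side <- list(name = phantom@name, voxel_size_mm = phantom@voxelSize,
               total_activity_bq = sum(phantom@activity),
               materials = phantom@materials)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paste0(prefix, ".json"))
}

#' @rdname writePhantom
#' @export
readPhantom <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  labels <- readNiftiGrid(paste0(prefix, "_labels.nii.gz"))
  storage.mode(labels) <- "integer"
  new("Phantom",
      activity = readNiftiGrid(paste0(prefix, "_activity.nii.gz")),
      mu = readNiftiGrid(paste0(prefix, "_mu.nii.gz")),
      labels = labels, voxelSize = side$voxel_size_mm, name = side$name,
      materials = as.data.frame(side$materials))
}

#' Write / read windowed projections as NIfTI stacks with a JSON sidecar
#'
#' One `<prefix>_<window>.nii.gz` per window plus
#' `<prefix>_true_primary.nii.gz` / `<prefix>_true_scatter.nii.gz` and a
#' `<prefix>.json` sidecar holding windows, geometry, seed and histories.
#'
#' @param wp a [WindowedProjections-class].
#' @param prefix output path prefix.
#' @return `writeProjections`: invisibly, the sidecar path.
#'   `readProjections`: the [WindowedProjections-class].
#' @export
writeProjections <- function(wp, prefix) {
  g <- wp@geometry
  for (nm in names(wp@counts))
    writeNiftiGrid(wp@counts[[nm]], paste0(prefix, "_", nm, ".nii.gz"),
                   g@binSize)
  writeNiftiGrid(wp@truePrimary, paste0(prefix, "_true_primary.nii.gz"),
                 g@binSize)
  writeNiftiGrid(wp@trueScatter, paste0(prefix, "_true_scatter.nii.gz"),
                 g@binSize)
  side <- list(windows = windowsToDF(wp@windows),
               geometry = list(nAngles = g@nAngles, arc = g@arc,
                               detectorBins = g@detectorBins,
                               binSize = g@binSize,
                               timePerView = g@timePerView),
               seed = wp@seed, histories = wp@histories,
               spectrum = wp@spectrum, spectrum_breaks = wp@spectrumBreaks)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paste0(prefix, ".json"))
}

#' @rdname writeProjections
#' @export
readProjections <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  windows <- dfToWindows(as.data.frame(side$windows))
  counts <- lapply(names(windows), function(nm)
    readNiftiGrid(paste0(prefix, "_", nm, ".nii.gz")))
  names(counts) <- names(windows)
  new("WindowedProjections", counts = counts,
      truePrimary = readNiftiGrid(paste0(prefix, "_true_primary.nii.gz")),
      trueScatter = readNiftiGrid(paste0(prefix, "_true_scatter.nii.gz")),
      spectrum = as.numeric(side$spectrum),
      spectrumBreaks = as.numeric(side$spectrum_breaks),
      geometry = do.call(acquisitionGeometry, as.list(side$geometry)),
      windows = windows, seed = side$seed, histories = side$histories)
}

#' Write a scatter estimate (NIfTI + JSON sidecar)
#'
#' @param estimate a [ScatterEstimate-class].
#' @param prefix output path prefix.
#' @param binSize detector bin size, mm.
#' @return invisibly, the sidecar path.
#' @export
writeScatterEstimate <- function(estimate, prefix, binSize = 4.8) {
  writeNiftiGrid(estimate@estimate, paste0(prefix, ".nii.gz"), binSize)
  jsonlite::write_json(list(method = estimate@method,
                            params = estimate@params,
                            clipped_bins = estimate@clippedBins),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}
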