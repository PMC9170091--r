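#' Experiment configuration
#'
#' The full comparison design: background media x correction methods on the
#' line-source phantom (SF/NMSE against the air reference), plus the uniform
#' cylinder for CV.  Defaults follow the evaluated protocol at desk scale:
#' 128 x 128 grid, 60 views, 1e6 histories per medium and seed.
#'
#' @param media TLSP background media; `"air"` is always included (it is
#'   the SF/NMSE reference).
#' @param corrections correction method strings (see [estimateScatter()]).
#' @param gridSize,voxelSize reconstruction/phantom grid.
#' @param histories photon histories per simulation.
#' @param seeds integer seeds; one independent realization per seed (the 2D
#'   surrogate of the 10-slice average).
#' @param geometry an [AcquisitionGeometry-class].
#' @param iterations,subsets OSEM protocol.
#' @param mode `"subtract_clip"` or `"additive_model"` (see
#'   [applyCorrection()]).
#' @param roiDiameterMM central ROI diameter for SF/NMSE on the TLSP, mm.
#' @param cvRoiFraction CV ROI diameter as a fraction of the uniform
#'   cylinder diameter (the "80% circular ROI").
#' @param includeUniform run the uniform-cylinder CV arm.
#' @param esseDepthsMM,esseHistories ESSE kernel-fit point-response settings.
#' @param psfFwhm optional resolution-recovery FWHM, mm.
#' @return list of class `ExperimentConfig`.
#' @export
experimentConfig <- function(media = c("air", "water", "k2hpo4"),
                             corrections = c("none", "dew5", "dew10",
                                             "dew15", "dew20", "tew3",
                                             "tew5", "tew7", "tew10",
                                             "esse"),
                             gridSize = 128, voxelSize = 4.8,
                             histories = 1e6, seeds = 1:10,
                             geometry = acquisitionGeometry(),
                             iterations = 2, subsets = 15,
                             mode = "subtract_clip",
                             roiDiameterMM = 150, cvRoiFraction = 0.8,
                             includeUniform = TRUE,
                             esseDepthsMM = c(0, 40, 80),
                             esseHistories = 1e6, psfFwhm = NULL) {
  media <- unique(c("air", media))
  known <- c("none", "truth", paste0("dew", c(5, 10, 15, 20)),
             paste0("tew", c(3, 5, 7, 10)), "esse")
  bad <- setdiff(corrections, known)
  if (length(bad)) stop("unknown correction method(s): ",
                        paste(bad, collapse = ", "))
  structure(list(media = media, corrections = corrections,
                 gridSize = gridSize, voxelSize = voxelSize,
                 histories = histories, seeds = as.integer(seeds),
                 geometry = geometry, iterations = iterations,
                 subsets = subsets, mode = mode,
                 roiDiameterMM = roiDiameterMM,
                 cvRoiFraction = cvRoiFraction,
                 includeUniform = includeUniform,
                 esseDepthsMM = esseDepthsMM,
                 esseHistories = esseHistories, psfFwhm = psfFwhm),
            class = "ExperimentConfig")
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experimentConfig()]; a nested
#' `geometry:` block maps to [acquisitionGeometry()].
#'
#' @param path YAML file path.
#' @return list of class `ExperimentConfig`.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$geometry)) y$geometry <- do.call(acquisitionGeometry,
                                                  y$geometry)
  do.call(experimentConfig, y)
}

configHash <- function(config) {
  plain <- lapply(unclass(config), function(x)
    if (isS4(x))
      list(nAngles = x@nAngles, arc = x@arc, detectorBins = x@detectorBins,
           binSize = x@binSize, timePerView = x@timePerView) else x)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = 12), f)
  unname(tools::md5sum(f))
}

# Derived seed for (medium index, seed index); kept well below 2^31.
derivedSeed <- function(baseSeed, mediumIdx, what = 0L) {
  as.integer((baseSeed + 7919L * mediumIdx + 104729L * what) %% .Machine$integer.max)
}

#' Run the full correction-comparison matrix
#'
#' For every medium and seed, simulates the TLSP once with all windows,
#' then for every correction method estimates and applies the scatter
#' correction, reconstructs with attenuated OSEM, and computes ROI counts;
#' SF and NMSE are evaluated against the air reference processed with the
#' same correction.  When `includeUniform` is set, the uniform K2HPO4
#' cylinder is run through the same corrections for CV.  Deterministic
#' given the seeds.
#'
#' @param config an `ExperimentConfig`.
#' @param verbose print per-stage progress.
#' @return list of class `ResultTable`: `sf_table` (medium, method,
#'   sf_percent, nmse_percent, t_counts, clipped_bins), `cv_table` (method,
#'   cv_percent), `images` (mean reconstruction per medium/method),
#'   `provenance` (config hash, seeds, package version).
#' @export
runMatrix <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "ExperimentConfig"))
  geo <- config$geometry
  roi <- circularROI(config$roiDiameterMM, slices = length(config$seeds))
  say <- function(...) if (verbose) message(sprintf(...))

  kernels <- NULL
  if ("esse" %in% config$corrections) {
    say("fitting ESSE kernels (%d point responses)",
        length(config$esseDepthsMM))
    pr <- essePointResponses(config$esseDepthsMM,
                             histories = config$esseHistories,
                             seed = derivedSeed(config$seeds[1], 0L, 99L),
                             gridSize = config$gridSize,
                             voxelSize = config$voxelSize, geometry = geo)
    kernels <- esseFitKernels(pr)
  }

  reconOne <- function(wp, phantom, method) {
    est <- estimateScatter(wp, method, kernels = kernels,
                           mu = attenuationMap(phantom),
                           voxelSize = config$voxelSize)
    co <- applyCorrection(wp, est, config$mode)
    img <- osem(co$counts, attenuationMap(phantom), geo,
                nIterations = config$iterations, nSubsets = config$subsets,
                scatterAdditive = co$scatterAdditive,
                psfFwhm = config$psfFwhm, voxelSize = config$voxelSize)
    list(values = reconValues(img), clipped = clippedBins(co$estimate))
  }

  # TLSP arm: mean reconstruction per (medium, method) over seeds
  images <- list()
  clipped <- list()
  for (mi in seq_along(config$media)) {
    medium <- config$media[mi]
    phantom <- buildTLSP(medium, config$gridSize, config$voxelSize)
    acc <- list()
    for (si in seq_along(config$seeds)) {
      sd <- derivedSeed(config$seeds[si], mi)
      say("simulate TLSP %s seed %d (%g histories)", medium, sd,
          config$histories)
      wp <- simulateProjections(phantom, geometry = geo,
                                histories = config$histories, seed = sd)
      for (method in config$corrections) {
        r <- reconOne(wp, phantom, method)
        key <- paste(medium, method, sep = ".")
        acc[[key]] <- (acc[[key]] %||% 0) + r$values / length(config$seeds)
        clipped[[key]] <- (clipped[[key]] %||% 0) + r$clipped
      }
    }
    for (key in names(acc)) attr(acc[[key]], "voxelSize") <- config$voxelSize
    images <- c(images, acc)
  }

  rows <- list()
  for (medium in config$media) {
    for (method in config$corrections) {
      key <- paste(medium, method, sep = ".")
      refKey <- paste("air", method, sep = ".")
      tMed <- roiCounts(images[[key]], roi)
      tAir <- roiCounts(images[[refKey]], roi)
      rows[[key]] <- data.frame(
        medium = medium, method = method,
        sf_percent = scatterFraction(tMed, tAir),
        nmse_percent = nmse(roiPixels(images[[refKey]], roi),
                            roiPixels(images[[key]], roi)),
        t_counts = tMed, clipped_bins = clipped[[key]],
        stringsAsFactors = FALSE)
    }
  }
  sfTable <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  cvTable <- NULL
  if (isTRUE(config$includeUniform)) {
    uni <- buildUniformCylinder(config$gridSize, config$voxelSize)
    cvRoi <- circularROI(config$cvRoiFraction * 160,
                         slices = length(config$seeds))
    acc <- list()
    for (si in seq_along(config$seeds)) {
      sd <- derivedSeed(config$seeds[si], length(config$media) + 1L)
      say("simulate uniform cylinder seed %d", sd)
      wp <- simulateProjections(uni, geometry = geo,
                                histories = config$histories, seed = sd)
      for (method in config$corrections) {
        r <- reconOne(wp, uni, method)
        acc[[method]] <- (acc[[method]] %||% 0) +
          r$values / length(config$seeds)
      }
    }
    cvTable <- do.call(rbind, lapply(config$corrections, function(m) {
      img <- acc[[m]]
      attr(img, "voxelSize") <- config$voxelSize
      data.frame(method = m, cv_percent = as.numeric(cv(img, cvRoi)),
                 stringsAsFactors = FALSE)
    }))
    for (m in names(acc)) images[[paste("uniform", m, sep = ".")]] <- acc[[m]]
  }

  structure(list(sf_table = sfTable, cv_table = cvTable, images = images,
                 roi = roi,
                 provenance = list(config_hash = configHash(config),
                                   seeds = config$seeds,
                                   voxel_size = config$voxelSize,
                                   package_version =
                                     as.character(utils::packageVersion("spectscatter")))),
            class = "ResultTable")
}

#' Render a result table to CSV and figures
#'
#' Writes `sf_nmse.csv` and `cv.csv`, bar plots of SF, NMSE and CV per
#' method and medium, and (when the reconstructions are present) a
#' residual-scatter panel of every method against the DEW 20% reference,
#' positive residual rendered in increasing red intensity.
#'
#' @param result a `ResultTable` from [runMatrix()].
#' @param outDir output directory (created if missing).
#' @param referenceMethod reference for the residual panel.
#' @return invisibly, the paths written.
#' @export
reportResults <- function(result, outDir, referenceMethod = "dew20") {
  stopifnot(inherits(result, "ResultTable"))
  if (nrow(result$sf_table) == 0) stop("empty table")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  w <- function(p) { paths <<- c(paths, p); p }

  utils::write.csv(result$sf_table, w(file.path(outDir, "sf_nmse.csv")),
                   row.names = FALSE)
  if (!is.null(result$cv_table))
    utils::write.csv(result$cv_table, w(file.path(outDir, "cv.csv")),
                     row.names = FALSE)

  barOne <- function(fname, valueCol, main) {
    tab <- result$sf_table[result$sf_table$medium != "air", ]
    grDevices::png(w(file.path(outDir, fname)), width = 900, height = 500)
    media <- unique(tab$medium)
    methods <- unique(tab$method)
    m <- t(vapply(media, function(md)
      tab[[valueCol]][match(methods, tab$method[tab$medium == md])],
      numeric(length(methods))))
    graphics::barplot(m, beside = TRUE, names.arg = methods,
                      legend.text = media, main = main, las = 2)
    grDevices::dev.off()
  }
  barOne("sf_barplot.png", "sf_percent", "Scatter fraction (%)")
  barOne("nmse_barplot.png", "nmse_percent", "NMSE (%)")
  if (!is.null(result$cv_table)) {
    grDevices::png(w(file.path(outDir, "cv_barplot.png")),
                   width = 700, height = 500)
    graphics::barplot(result$cv_table$cv_percent,
                      names.arg = result$cv_table$method, las = 2,
                      main = "Uniform cylinder CV (%)")
    grDevices::dev.off()
  }

  refKeys <- grep(paste0("\\.", referenceMethod, "$"), names(result$images),
                  value = TRUE)
  if (length(refKeys)) {
    media <- setdiff(unique(result$sf_table$medium), "air")
    methods <- setdiff(unique(result$sf_table$method), referenceMethod)
    grDevices::png(w(file.path(outDir, "residual_panel.png")),
                   width = 250 * max(1, length(methods)),
                   height = 250 * max(1, length(media)))
    graphics::par(mfrow = c(max(1, length(media)), max(1, length(methods))),
                  mar = c(1, 1, 2, 1))
    reds <- grDevices::colorRampPalette(c("white", "red"))(64)
    for (md in media) {
      ref <- result$images[[paste(md, referenceMethod, sep = ".")]]
      for (mt in methods) {
        img <- result$images[[paste(md, mt, sep = ".")]]
        if (is.null(img) || is.null(ref)) next
        res <- pmax(img - ref, 0)
        graphics::image(res, col = reds, axes = FALSE,
                        main = paste(md, mt, "-", referenceMethod))
      }
    }
    grDevices::dev.off()
  }
  invisible(paths)
}
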