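# File interfaces: NIfTI image series with JSON timing sidecars, contour
# JSON, tidy curve CSV, trajectory CSV, and cohort report bundles.

#' Write an encoded series to NIfTI + JSON sidecar
#'
#' One 3-D NIfTI volume per phase set (ref, x, y, z) plus the magnitude,
#' with frame times, RR interval and acquisition parameters in a JSON
#' sidecar.
#'
#' @param encoded an \linkS4class{EncodedSeries}
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
writeEncodedSeries <- function(encoded, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sets <- c("ref", "x", "y", "z")
  for (i in seq_along(sets)) {
    RNifti::writeNifti(encoded@phases[, , , i],
                       file.path(dir, paste0("phase_", sets[i], ".nii.gz")))
  }
  RNifti::writeNifti(encoded@magnitude, file.path(dir, "magnitude.nii.gz"))
  p <- encoded@params
  side <- list(
    frameTimes = encoded@frameTimes,
    rrInterval = p@rrInterval,
    pixelSpacing = encoded@pixelSpacing,
    params = list(
      vencThroughPlane = p@vencThroughPlane, vencInPlane = p@vencInPlane,
      nInterleaves = p@nInterleaves,
      spiralReadoutDuration = p@spiralReadoutDuration,
      temporalResolution = p@temporalResolution, fov = p@fov,
      matrixSize = p@matrixSize,
      nReconstructedPhases = p@nReconstructedPhases,
      sliceThickness = p@sliceThickness, navigatorWindow = p@navigatorWindow
    )
  )
  jsonlite::write_json(side, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an encoded series written by \code{\link{writeEncodedSeries}}
#'
#' @param dir directory containing the NIfTI volumes and sidecar
#' @return an \linkS4class{EncodedSeries}
#' @export
readEncodedSeries <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  sets <- c("ref", "x", "y", "z")
  vols <- lapply(sets, function(s) {
    v <- RNifti::readNifti(file.path(dir, paste0("phase_", s, ".nii.gz")))
    array(as.numeric(v), dim = dim(v))
  })
  d <- dim(vols[[1]])
  phases <- array(0, dim = c(d, 4))
  for (i in 1:4) phases[, , , i] <- vols[[i]]
  magIn <- RNifti::readNifti(file.path(dir, "magnitude.nii.gz"))
  mag <- array(as.numeric(magIn), dim = dim(magIn))
  pl <- side$params
  params <- AcquisitionParams(
    vencThroughPlane = pl$vencThroughPlane, vencInPlane = pl$vencInPlane,
    nInterleaves = pl$nInterleaves,
    spiralReadoutDuration = pl$spiralReadoutDuration,
    temporalResolution = pl$temporalResolution, fov = pl$fov,
    matrixSize = pl$matrixSize,
    nReconstructedPhases = pl$nReconstructedPhases,
    sliceThickness = pl$sliceThickness, navigatorWindow = pl$navigatorWindow,
    rrInterval = side$rrInterval
  )
  new("EncodedSeries",
    magnitude = mag, phases = wrapPhase(phases), frameTimes = side$frameTimes,
    params = params, pixelSpacing = side$pixelSpacing
  )
}

#' Write contours and landmark as JSON
#'
#' @param contours list with `endo`, `epi` (per-frame matrices) and
#'   `landmark`
#' @param path output JSON path
#' @return invisibly, the path
#' @export
writeContoursJSON <- function(contours, path) {
  asXY <- function(m) list(x = m[, 1], y = m[, 2])
  obj <- list(
    landmark = contours$landmark,
    endo = lapply(contours$endo, asXY),
    epi = lapply(contours$epi, asXY)
  )
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read contours written by \code{\link{writeContoursJSON}}
#'
#' @param path JSON path
#' @return list with `endo`, `epi`, `landmark`
#' @export
readContoursJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fromXY <- function(o) cbind(as.numeric(unlist(o$x)), as.numeric(unlist(o$y)))
  list(
    endo = lapply(obj$endo, fromXY),
    epi = lapply(obj$epi, fromXY),
    landmark = as.numeric(unlist(obj$landmark))
  )
}

#' Export velocity-time curves as tidy CSV
#'
#' Columns: region, direction, time_ms, velocity_cm_s.
#'
#' @param curves list of \linkS4class{VelocityTimeCurve}s
#' @param path output CSV path
#' @return invisibly, the path
#' @export
writeCurvesCSV <- function(curves, path) {
  rows <- lapply(curves, function(cu) {
    data.frame(region = cu@region, direction = cu@direction,
               time_ms = cu@times, velocity_cm_s = cu@values)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export a spiral trajectory as CSV
#'
#' Columns: interleave, kx, ky (cycles/mm), t_ms.
#'
#' @param trajectory a \linkS4class{SpiralTrajectory}
#' @param path output CSV path
#' @return invisibly, the path
#' @export
exportTrajectoryCSV <- function(trajectory, path) {
  utils::write.csv(
    data.frame(interleave = trajectory@interleave, kx = trajectory@kx,
               ky = trajectory@ky, t_ms = trajectory@times),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Write a colour grid as CSV
#'
#' One row per angular segment (anterior first), one column per template
#' time.
#'
#' @param grid a \linkS4class{ColourGrid}
#' @param path output CSV path
#' @return invisibly, the path
#' @export
writeColourGridCSV <- function(grid, path) {
  m <- grid@values
  rownames(m) <- sprintf("seg%02d", seq_len(24))
  colnames(m) <- sprintf("t%.1f", grid@times)
  utils::write.csv(m, path)
  invisible(path)
}

#' Write the cohort report bundle
#'
#' Curve CSVs, peak/TTP tables, colour grids, the reproducibility table
#' (when present) and a JSON run log echoing the configuration and
#' package version.
#'
#' @param result the list returned by \code{\link{runCohort}}
#' @param dir output directory
#' @return invisibly, the directory
#' @export
writeCohortOutputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # peak tables per visit
  for (vKey in names(result$peaks)) {
    tabs <- lapply(names(result$peaks[[vKey]]), function(s) {
      do.call(rbind, lapply(result$peaks[[vKey]][[s]], function(ps) {
        p <- ps@peaks
        p$subject <- s
        p$direction <- ps@direction
        p
      }))
    })
    utils::write.csv(do.call(rbind, tabs),
                     file.path(dir, paste0("peaks_", vKey, ".csv")),
                     row.names = FALSE)
  }
  # global curves of visit 1
  curves <- unlist(lapply(result$subjects, function(subj) {
    subj[[1]]$analysis$curves
  }), recursive = FALSE)
  writeCurvesCSV(curves, file.path(dir, "global_curves_visit1.csv"))
  for (d in names(result$colourGrids)) {
    writeColourGridCSV(result$colourGrids[[d]],
                       file.path(dir, paste0("colour_grid_", d, ".csv")))
  }
  if (!is.null(result$reproducibility)) {
    utils::write.csv(result$reproducibility,
                     file.path(dir, "reproducibility.csv"), row.names = FALSE)
  }
  cm <- lapply(result$cycleMeans, function(m) {
    stats::setNames(as.data.frame(m),
                    c("longitudinal", "radial", "circumferential"))
  })
  log <- list(
    package = "spiralPVM",
    version = as.character(utils::packageVersion("spiralPVM")),
    config = result$config[setdiff(names(result$config), "outDir")],
    cycleMeans = cm
  )
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
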