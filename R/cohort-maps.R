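# Four-section cardiac-phase normalization, cohort averaging, and the
# 24-segment by time colour grids.

#' Cardiac phase normalization template
#'
#' Target lengths for the four sections used in phase normalization.
#' Systole defaults to the cohort-average 350 ms; the 650 ms diastole is
#' split into early diastole (150 ms), diastasis (300 ms) and atrial
#' systole (200 ms).
#'
#' @param systole,earlyDiastole,diastasis,atrialSystole section lengths, ms
#' @param nPoints output samples per cycle
#' @return a \linkS4class{PhaseTemplate}
#' @export
phaseTemplate <- function(systole = 350, earlyDiastole = 150,
                          diastasis = 300, atrialSystole = 200,
                          nPoints = 60) {
  new("PhaseTemplate",
    sectionLengths = c(systole = systole, early_diastole = earlyDiastole,
                       diastasis = diastasis, atrial_systole = atrialSystole),
    nPoints = nPoints
  )
}

#' @describeIn phaseTemplate section boundary times of a template, ms
#'   (end systole, diastasis onset, atrial onset, cycle end)
#' @param template a PhaseTemplate
#' @export
templateBoundaries <- function(template) {
  cumsum(template@sectionLengths)
}

#' @describeIn phaseTemplate the uniform output time grid of a template, ms
#' @export
templateTimes <- function(template) {
  total <- sum(template@sectionLengths)
  (seq_len(template@nPoints) - 1) * total / template@nPoints
}

setMethod("show", "PhaseTemplate", function(object) {
  cat(sprintf(
    "PhaseTemplate: %g/%g/%g/%g ms sections, %g points/cycle\n",
    object@sectionLengths[1], object@sectionLengths[2],
    object@sectionLengths[3], object@sectionLengths[4], object@nPoints
  ))
})

#' Normalize a velocity-time curve to the phase template
#'
#' Each of the four sections (systole, early diastole, diastasis, atrial
#' systole, delimited by the curve's own phase markers) is mapped by a
#' monotone piecewise-linear time warp onto its template length; values
#' are resampled by shape-preserving piecewise-cubic interpolation
#' (Fritsch-Carlson monotone Hermite by default; plain natural cubic via
#' `method`). The marker times are inserted as knots, so section boundary
#' values are preserved exactly. The curve is closed cyclically at the
#' R-wave.
#'
#' @param curve a \linkS4class{VelocityTimeCurve} covering one cycle
#' @param markers the curve's \linkS4class{CardiacPhaseMarkers}
#' @param template a \linkS4class{PhaseTemplate}
#' @param method "pchip" (shape-preserving) or "natural" cubic
#' @return a \linkS4class{VelocityTimeCurve} on the template grid
#' @export
normalizeCurve <- function(curve, markers, template = phaseTemplate(),
                           method = c("pchip", "natural")) {
  method <- match.arg(method)
  rr <- curve@rrInterval
  if (abs(markers@rrInterval - rr) > 1e-6) {
    stop("markers do not belong to this curve (RR mismatch)")
  }
  bIn <- c(0, markers@tEndSystole, markers@tDiastasisOnset,
           markers@tAtrialOnset, rr)
  if (any(bIn < min(curve@times) - 1e-9) || any(bIn > rr + 1e-9)) {
    stop("markers outside the curve support")
  }
  bOut <- c(0, templateBoundaries(template))

  tIn <- curve@times
  vIn <- curve@values
  if (max(tIn) < rr) {  # close the cycle at the R-wave
    tIn <- c(tIn, rr)
    vIn <- c(vIn, vIn[1])
  }
  fun <- function(x, y) {
    if (method == "pchip") {
      stats::splinefun(x, y, method = "monoH.FC")
    } else {
      stats::splinefun(x, y, method = "natural")
    }
  }
  baseInterp <- fun(tIn, vIn)
  newKnots <- setdiff(round(bIn, 9), round(tIn, 9))
  if (length(newKnots) > 0) {
    tIn <- c(tIn, newKnots)
    vIn <- c(vIn, baseInterp(newKnots))
    o <- order(tIn)
    tIn <- tIn[o]; vIn <- vIn[o]
  }

  tWarp <- stats::approx(bIn, bOut, xout = tIn, rule = 2)$y
  interp <- fun(tWarp, vIn)
  tOut <- templateTimes(template)
  new("VelocityTimeCurve",
    region = curve@region, direction = curve@direction,
    times = tOut, values = interp(tOut),
    rrInterval = sum(template@sectionLengths)
  )
}

#' Pointwise group average of normalized curves
#'
#' @param curves list of \linkS4class{VelocityTimeCurve}s on a common
#'   (template) time grid
#' @return list with `mean` (a \linkS4class{VelocityTimeCurve}) and `sd`
#'   (pointwise standard deviation)
#' @export
groupAverage <- function(curves) {
  if (length(curves) < 1) stop("no curves to average")
  t0 <- curves[[1]]@times
  for (cu in curves) {
    if (length(cu@times) != length(t0) || any(abs(cu@times - t0) > 1e-9)) {
      stop("curves are not on a common time grid")
    }
  }
  vals <- vapply(curves, function(cu) cu@values, numeric(length(t0)))
  vals <- matrix(vals, nrow = length(t0))
  mn <- rowMeans(vals)
  sdv <- if (ncol(vals) > 1) apply(vals, 1, stats::sd) else rep(0, length(t0))
  list(
    mean = new("VelocityTimeCurve",
      region = curves[[1]]@region, direction = curves[[1]]@direction,
      times = t0, values = mn, rrInterval = curves[[1]]@rrInterval
    ),
    sd = sdv
  )
}

#' Build a 24-segment colour grid
#'
#' Stacks 24 normalized equal-angle segment curves into a 24 x T grid,
#' rows ordered anterior -> lateral -> inferior -> septal (increasing
#' theta from the anterior junction), with the template section boundary
#' columns recorded for plotting.
#'
#' @param curves list of exactly 24 normalized
#'   \linkS4class{VelocityTimeCurve}s, ordered by segment (seg01..seg24)
#' @param direction velocity direction label
#' @param sliceLevel slice level label
#' @param template the \linkS4class{PhaseTemplate} used for normalization
#' @return a \linkS4class{ColourGrid}
#' @export
buildColourGrid <- function(curves, direction, sliceLevel,
                            template = phaseTemplate()) {
  if (length(curves) != 24) {
    stop("a colour grid requires exactly 24 segment curves")
  }
  t0 <- templateTimes(template)
  vals <- t(vapply(curves, function(cu) {
    if (length(cu@values) != length(t0)) {
      stop("curves are not on the template grid")
    }
    cu@values
  }, numeric(length(t0))))
  bounds <- templateBoundaries(template)[1:3]
  mk <- unname(vapply(bounds, function(b) which(t0 >= b - 1e-9)[1], integer(1)))
  new("ColourGrid",
    values = vals, direction = direction, sliceLevel = sliceLevel,
    times = t0, markerIndices = mk
  )
}

#' @describeIn buildColourGrid numeric values of a colour grid
#' @param x a ColourGrid
#' @export
setMethod("gridValues", "ColourGrid", function(x) x@values)

setMethod("show", "ColourGrid", function(object) {
  cat(sprintf(
    "ColourGrid (%s, %s slice): 24 segments x %d phases, |v| max %.2f cm/s\n",
    object@direction, object@sliceLevel, ncol(object@values),
    max(abs(object@values))
  ))
})

#' Plot a colour grid
#'
#' Renders the 24-segment by time colour map with a symmetric colour scale
#' about zero and vertical lines at the section boundaries; anterior at
#' the top, proceeding through lateral, inferior and septal. Rendering is
#' isolated from the numeric grid so analyses stay headless.
#'
#' @param grid a \linkS4class{ColourGrid}
#' @param file optional PNG path; when NULL, draws on the current device
#' @return invisibly, the symmetric colour limit used (cm/s)
#' @export
plotColourGrid <- function(grid, file = NULL) {
  lim <- max(abs(grid@values))
  if (lim == 0) lim <- 1
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::colorRampPalette(
    c("#2166AC", "#F7F7F7", "#B2182B")
  )(101)
  # row 1 (anterior) at the top
  z <- t(grid@values[rev(seq_len(24)), , drop = FALSE])
  graphics::image(
    x = grid@times, y = seq_len(24), z = z[, , drop = FALSE],
    zlim = c(-lim, lim), col = pal,
    xlab = "time from R-wave (ms)", ylab = "segment (septal -> anterior)",
    main = sprintf("%s velocity, %s slice", grid@direction, grid@sliceLevel)
  )
  graphics::abline(v = grid@times[grid@markerIndices], lwd = 2)
  invisible(lim)
}
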