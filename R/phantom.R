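# Synthetic moving-annulus phantom: rasterized ground-truth velocity fields,
# contours, phase encoding and the stationary background-correction series.

#' Render ground-truth velocity frames of the annulus phantom
#'
#' Rasterizes the motion model on a pixel grid: a myocardial annulus
#' (concentric circles at end-diastole) whose radii follow the integrated
#' global radial velocity, with per-pixel velocities evaluated at each
#' pixel's angular coordinate and transmural depth. Pixels outside the
#' myocardium have zero velocity. The anterior LV-RV junction landmark sits
#' just outside the epicardium along the image "up" direction; the slice is
#' viewed from the apex, so the circumferential-positive sense is clockwise
#' on screen.
#'
#' @param model a \linkS4class{MotionModel}
#' @param params an \linkS4class{AcquisitionParams} (pixel spacing =
#'   fov/matrix)
#' @param gridSize pixel grid size; defaults to the full acquisition matrix.
#'   Smaller grids crop the field of view at unchanged pixel spacing.
#' @param times frame times in ms; defaults to the acquired frame grid
#'   (0, dt, 2*dt, ... < rr)
#' @param endoRadius,epiRadius end-diastolic annulus radii, mm
#' @return list with `velocity` (\linkS4class{VelocityFieldSeries} of the
#'   true field), `endo`, `epi` (per-frame contour matrices, mm), `landmark`
#'   (x, y in mm), `mask` (analytic annulus mask, rows x cols x frames), and
#'   `groundTruth` (prescribed peaks, markers, model)
#' @export
renderVelocityFrames <- function(model, params = AcquisitionParams(),
                                 gridSize = NULL, times = NULL,
                                 endoRadius = 20, epiRadius = 30) {
  if (endoRadius >= epiRadius) {
    stop("annulus radii inverted: endoRadius must be smaller than epiRadius")
  }
  spacing <- pixelSpacing(params)
  n <- if (is.null(gridSize)) params@matrixSize else gridSize
  if (2 * epiRadius >= n * spacing) {
    stop("annulus does not fit inside the pixel grid")
  }
  rr <- model@rrInterval
  if (is.null(times)) {
    times <- seq(0, rr - 1e-9, by = params@temporalResolution)
  }
  wallPx <- (epiRadius - endoRadius) / spacing
  if (wallPx < 3) {
    warning(sprintf("myocardial wall spans only %.1f pixels", wallPx))
  }

  g <- model@transmuralGradient
  radii <- .annulusRadii(model, times, endoRadius, epiRadius)

  grid <- pixelGrid(c(n, n), spacing)
  r <- sqrt(grid$x^2 + grid$y^2)
  ref <- c(0, -1)
  th <- matrix(angleFromReference(as.vector(grid$x), as.vector(grid$y), ref),
               n, n)
  modAngular <- 1 + model@regional$depth * cos(th - model@regional$phase)

  nf <- length(times)
  vel <- array(0, dim = c(n, n, nf, 3))
  mask <- array(FALSE, dim = c(n, n, nf))
  contours <- annulusContours(model, times, endoRadius, epiRadius)

  fL <- velocityProfile(model, "longitudinal", times)
  fRt <- velocityProfile(model, "radial", times)
  fC <- velocityProfile(model, "circumferential", times)

  for (k in seq_len(nf)) {
    rEndo <- radii$endo[k]
    rEpi <- radii$epi[k]
    m <- r >= rEndo & r <= rEpi & r > 0
    mask[, , k] <- m
    d <- pmin(pmax((r - rEndo) / (rEpi - rEndo), 0), 1)
    # per-frame calibration: normalise the spatial modulation to unit
    # mask mean so the volume-averaged velocity equals the prescribed
    # global profile exactly (the prescribed amplitudes are global
    # region averages)
    facRad <- modAngular * (1 + g * (0.5 - d))
    facRad <- facRad / mean(facRad[m])
    facAng <- modAngular / mean(modAngular[m])
    vRad <- fRt[k] * facRad
    vCirc <- fC[k] * facAng
    vLong <- fL[k] * facAng
    rhx <- grid$x / pmax(r, 1e-9)
    rhy <- grid$y / pmax(r, 1e-9)
    vx <- (-vRad * rhx - vCirc * rhy) * m
    vy <- (-vRad * rhy + vCirc * rhx) * m
    vel[, , k, 1] <- vx
    vel[, , k, 2] <- vy
    vel[, , k, 3] <- vLong * m
  }

  truth <- new("VelocityFieldSeries",
    velocities = vel, times = times, rrInterval = rr, pixelSpacing = spacing
  )
  list(
    velocity = truth, endo = contours$endo, epi = contours$epi,
    landmark = contours$landmark, mask = mask,
    groundTruth = list(
      peaks = modelPeaks(model), markers = modelMarkers(model), model = model
    )
  )
}

# Endo/epi radii over time: end-diastolic radii minus the integrated
# global radial velocity, with the transmural factor at the respective
# surface (depth 0 endo, 1 epi).
.annulusRadii <- function(model, times, endoRadius, epiRadius) {
  rr <- model@rrInterval
  g <- model@transmuralGradient
  tFine <- seq(0, rr, by = 1)
  fR <- velocityProfile(model, "radial", tFine)
  disp <- 0.01 * cumtrapz(tFine, fR)  # cm/s * ms -> mm, inward positive
  dAt <- stats::approx(tFine, disp, xout = times %% rr, rule = 2)$y
  list(endo = endoRadius - (1 + 0.5 * g) * dAt,
       epi = epiRadius - (1 - 0.5 * g) * dAt)
}

#' Analytic annulus contours of the phantom at given times
#'
#' Ground-truth endocardial and epicardial contours (72-vertex circles)
#' whose radii follow the integrated global radial velocity of the model,
#' plus the anterior LV-RV junction landmark. These play the role of the
#' manually drawn contours of an in vivo analysis and can be evaluated at
#' any time, e.g. the retrospectively reconstructed phase grid.
#'
#' @param model a \linkS4class{MotionModel}
#' @param times frame times, ms
#' @param endoRadius,epiRadius end-diastolic radii, mm
#' @return list with `endo`, `epi` (per-frame contour matrices, mm) and
#'   `landmark` (x, y in mm)
#' @export
annulusContours <- function(model, times, endoRadius = 20, epiRadius = 30) {
  if (endoRadius >= epiRadius) {
    stop("annulus radii inverted: endoRadius must be smaller than epiRadius")
  }
  radii <- .annulusRadii(model, times, endoRadius, epiRadius)
  phis <- seq(0, 2 * pi, length.out = 73)[-73]
  circleAt <- function(radius) {
    cbind(radius * sin(phis), -radius * cos(phis))  # starts at the landmark
  }
  list(
    endo = lapply(radii$endo, circleAt),
    epi = lapply(radii$epi, circleAt),
    landmark = c(0, -(epiRadius + 2))
  )
}

#' Random smooth background phase coefficients
#'
#' Draws second-order 2-D polynomial coefficients (terms 1, x, y, x^2, xy,
#' y^2 on coordinates normalised to [-1, 1]) for each of the four phase
#' sets, emulating the smooth spatially varying background phase measured
#' on a stationary phantom.
#'
#' @param seed integer seed
#' @param scale multiplier on the default coefficient spread
#' @return a 4 x 6 matrix with rows c("ref", "x", "y", "z")
#' @export
randomBackgroundCoeffs <- function(seed = NULL, scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  sds <- c(0.15, 0.08, 0.08, 0.05, 0.05, 0.05) * scale
  m <- matrix(stats::rnorm(24, 0, rep(sds, each = 4)), 4, 6)
  rownames(m) <- c("ref", "x", "y", "z")
  colnames(m) <- c("c0", "cx", "cy", "cxx", "cxy", "cyy")
  m
}

# Evaluate one background polynomial on an n x n grid.
.backgroundField <- function(coeffs, n) {
  u <- seq(-1, 1, length.out = n)
  X <- matrix(rep(u, each = n), n, n)
  Y <- matrix(rep(u, times = n), n, n)
  coeffs[1] + coeffs[2] * X + coeffs[3] * Y +
    coeffs[4] * X^2 + coeffs[5] * X * Y + coeffs[6] * Y^2
}

#' Encode a velocity field series into phase images
#'
#' Applies the linear phase-contrast mapping phi = pi * v / venc (phase pi
#' at venc) per component: the reference set carries only its background
#' field, each encoded set carries its background plus the velocity phase
#' (through-plane venc for z, in-plane venc for x and y). Independent
#' Gaussian phase noise is added to every set and the result is wrapped to
#' [-pi, pi). Velocities at or beyond venc are rejected.
#'
#' @param truth a \linkS4class{VelocityFieldSeries} (the true field)
#' @param params an \linkS4class{AcquisitionParams}
#' @param backgroundCoeffs 4 x 6 coefficient matrix as from
#'   \code{\link{randomBackgroundCoeffs}}, or NULL for no background
#' @param noiseSd phase noise standard deviation, radians
#' @param seed integer seed for the noise
#' @param mask optional myocardial mask (rows x cols x frames) used to
#'   build the magnitude image (myocardium 1.0, cavity 0.1 emulating black
#'   blood, air 0); without it the magnitude is 1 everywhere
#' @param cavity optional logical cavity mask
#' @return an \linkS4class{EncodedSeries}
#' @export
encodePhases <- function(truth, params = AcquisitionParams(),
                         backgroundCoeffs = NULL, noiseSd = 0, seed = NULL,
                         mask = NULL, cavity = NULL) {
  v <- truth@velocities
  d <- dim(v)
  n <- d[1]
  vencs <- c(x = params@vencInPlane, y = params@vencInPlane,
             z = params@vencThroughPlane)
  for (c_i in 1:3) {
    if (max(abs(v[, , , c_i])) >= vencs[c_i]) {
      stop(sprintf(
        "velocity component '%s' reaches venc (%g cm/s); phase would wrap",
        names(vencs)[c_i], vencs[c_i]
      ))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  nf <- d[3]
  phases <- array(0, dim = c(n, n, nf, 4))
  sets <- c("ref", "x", "y", "z")
  for (s in 1:4) {
    bg <- if (is.null(backgroundCoeffs)) {
      matrix(0, n, n)
    } else {
      .backgroundField(backgroundCoeffs[s, ], n)
    }
    for (k in seq_len(nf)) {
      phi <- bg
      if (s > 1) phi <- phi + pi * v[, , k, s - 1] / vencs[s - 1]
      if (noiseSd > 0) phi <- phi + stats::rnorm(n * n, 0, noiseSd)
      phases[, , k, s] <- wrapPhase(phi)
    }
  }
  mag <- array(1, dim = c(n, n, nf))
  if (!is.null(mask)) {
    mag <- array(0, dim = c(n, n, nf))
    mag[mask] <- 1
    if (!is.null(cavity)) mag[cavity & !mask] <- 0.1
  }
  new("EncodedSeries",
    magnitude = mag, phases = phases, frameTimes = truth@times,
    params = params, pixelSpacing = truth@pixelSpacing
  )
}

#' Generate a stationary-phantom encoded series
#'
#' The background-correction input: the same frame grid and background
#' phase polynomial model as a subject acquisition, but zero true velocity
#' (a large homogeneous stationary phantom scanned with the same sequence).
#'
#' @param params an \linkS4class{AcquisitionParams}
#' @param gridSize pixel grid size (default: full matrix)
#' @param times frame times, ms (default: acquired frame grid)
#' @param backgroundCoeffs 4 x 6 coefficient matrix or NULL
#' @param noiseSd phase noise SD, radians
#' @param seed integer seed
#' @return an \linkS4class{EncodedSeries}
#' @export
generateStationarySeries <- function(params = AcquisitionParams(),
                                     gridSize = NULL, times = NULL,
                                     backgroundCoeffs = NULL, noiseSd = 0,
                                     seed = NULL) {
  n <- if (is.null(gridSize)) params@matrixSize else gridSize
  if (is.null(times)) {
    times <- seq(0, params@rrInterval - 1e-9, by = params@temporalResolution)
  }
  zero <- new("VelocityFieldSeries",
    velocities = array(0, dim = c(n, n, length(times), 3)),
    times = times, rrInterval = params@rrInterval,
    pixelSpacing = pixelSpacing(params)
  )
  encodePhases(zero, params, backgroundCoeffs, noiseSd, seed)
}

#' @describeIn encodePhases frame times of an encoded series, ms
#' @param x an EncodedSeries
#' @export
setMethod("frameTimes", "EncodedSeries", function(x) x@frameTimes)

#' @describeIn encodePhases pixel spacing of an encoded series, mm
#' @export
setMethod("pixelSpacing", "EncodedSeries", function(x) x@pixelSpacing)

setMethod("show", "EncodedSeries", function(object) {
  d <- dim(object@phases)
  cat(sprintf(
    "EncodedSeries: %d x %d pixels, %d frames, 4 phase sets (ref, x, y, z)\n",
    d[1], d[2], d[3]
  ))
  cat(sprintf("  frame times %.0f..%.0f ms of RR %.0f ms; pixel %.3g mm\n",
              min(object@frameTimes), max(object@frameTimes),
              object@params@rrInterval, object@pixelSpacing))
})

#' @describeIn renderVelocityFrames frame times of a velocity field series
#' @param x a VelocityFieldSeries
#' @export
setMethod("frameTimes", "VelocityFieldSeries", function(x) x@times)

#' @describeIn renderVelocityFrames velocity array of a field series
#' @export
setMethod("velocities", "VelocityFieldSeries", function(x) x@velocities)

#' @describeIn renderVelocityFrames cycle length, ms
#' @export
setMethod("rrInterval", "VelocityFieldSeries", function(x) x@rrInterval)

#' @describeIn renderVelocityFrames pixel spacing, mm
#' @export
setMethod("pixelSpacing", "VelocityFieldSeries", function(x) x@pixelSpacing)

setMethod("show", "VelocityFieldSeries", function(object) {
  d <- dim(object@velocities)
  cat(sprintf("VelocityFieldSeries: %d x %d pixels, %d frames x 3 components\n",
              d[1], d[2], d[3]))
  cat(sprintf("  times %.1f..%.1f ms of RR %.0f ms; max |v| %.2f cm/s\n",
              min(object@times), max(object@times), object@rrInterval,
              max(abs(object@velocities))))
})
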