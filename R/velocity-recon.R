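# Phase-difference velocity reconstruction, retrospective-gating
# interpolation and stationary-phantom background correction.

#' Convert encoded phase images to velocities
#'
#' Per pixel and frame, v_c = venc_c * wrap(phi_enc,c - phi_ref) / pi for
#' c in x, y, z, with the in-plane venc for x and y and the through-plane
#' venc for z; the difference is wrapped into [-pi, pi). No phase
#' unwrapping is attempted: myocardial velocities are assumed below venc,
#' and apparent wrap-through (velocity within 2 percent of venc) raises a
#' warning, not an error.
#'
#' @param encoded an \linkS4class{EncodedSeries}
#' @return a \linkS4class{VelocityFieldSeries} at the acquired frame times
#' @export
phaseDifferenceToVelocity <- function(encoded) {
  d <- dim(encoded@phases)
  if (length(d) != 4 || d[4] != 4) {
    stop("encoded series must carry four phase sets (ref, x, y, z)")
  }
  p <- encoded@params
  vencs <- c(p@vencInPlane, p@vencInPlane, p@vencThroughPlane)
  vel <- array(0, dim = c(d[1], d[2], d[3], 3))
  for (c_i in 1:3) {
    dphi <- wrapPhase(encoded@phases[, , , c_i + 1, drop = FALSE] -
                        encoded@phases[, , , 1, drop = FALSE])
    vel[, , , c_i] <- vencs[c_i] * dphi / pi
  }
  if (max(abs(vel)) > 0.98 * max(vencs)) {
    warning("velocities close to venc detected; phase wrap-through possible")
  }
  new("VelocityFieldSeries",
    velocities = vel, times = encoded@frameTimes,
    rrInterval = p@rrInterval, pixelSpacing = encoded@pixelSpacing
  )
}

#' Retrospective-gating interpolation to equally spaced cardiac phases
#'
#' Per-pixel linear interpolation of the acquired frames onto
#' t_k = k * rr / nPhases, k = 0..nPhases-1. The gap between the last
#' acquired frame and the first frame of the next cycle is interpolated
#' cyclically (retrospective gating closes the cycle).
#'
#' @param series a \linkS4class{VelocityFieldSeries} at acquired times
#' @param nPhases number of output phases
#' @return a \linkS4class{VelocityFieldSeries} on the uniform phase grid
#' @export
retroGateInterpolate <- function(series, nPhases = 60) {
  tAcq <- series@times
  if (length(tAcq) < 2) stop("at least two acquired frames are required")
  if (is.unsorted(tAcq, strictly = TRUE)) stop("frame times must be sorted")
  rr <- series@rrInterval
  tOut <- (seq_len(nPhases) - 1) * rr / nPhases
  nf <- length(tAcq)

  # bracketing indices on the cyclically extended time axis: frame nf is
  # repeated one cycle earlier and frame 1 one cycle later
  tExt <- c(tAcq[nf] - rr, tAcq, tAcq[1] + rr)
  lo <- findInterval(tOut, tExt, rightmost.closed = FALSE)
  hi2 <- lo + 1
  w <- (tOut - tExt[lo]) / (tExt[hi2] - tExt[lo])
  extToFrame <- function(e) ((e - 2) %% nf) + 1
  loIdx <- extToFrame(lo)
  hiIdx <- extToFrame(hi2)

  d <- dim(series@velocities)
  out <- array(0, dim = c(d[1], d[2], nPhases, 3))
  for (k in seq_len(nPhases)) {
    out[, , k, ] <- (1 - w[k]) * series@velocities[, , loIdx[k], ] +
      w[k] * series@velocities[, , hiIdx[k], ]
  }
  new("VelocityFieldSeries",
    velocities = out, times = tOut, rrInterval = rr,
    pixelSpacing = series@pixelSpacing
  )
}

#' Median-smooth a stationary background velocity map
#'
#' A 2-D median filter (default 5 x 5) applied per frame and velocity
#' component to the stationary-phantom velocity maps before subtraction,
#' reducing noise while preserving the smooth background structure.
#'
#' @param series a \linkS4class{VelocityFieldSeries} (stationary phantom)
#' @param kernelSize odd filter window size; 1 is the identity
#' @return the smoothed \linkS4class{VelocityFieldSeries}
#' @export
smoothBackgroundMap <- function(series, kernelSize = 5) {
  if (kernelSize %% 2 != 1 || kernelSize < 1) {
    stop("kernelSize must be an odd positive integer")
  }
  if (kernelSize == 1) return(series)
  v <- series@velocities
  d <- dim(v)
  for (k in seq_len(d[3])) {
    for (c_i in 1:3) {
      v[, , k, c_i] <- median_filter_2d(v[, , k, c_i], kernelSize)
    }
  }
  new("VelocityFieldSeries",
    velocities = v, times = series@times, rrInterval = series@rrInterval,
    pixelSpacing = series@pixelSpacing
  )
}

#' Average a velocity field series over its frames
#'
#' Replaces every frame by the across-frame mean. Used on the
#' stationary-phantom velocity maps before smoothing: the phantom's
#' background phase is static, so averaging its frames reduces the map
#' noise by the square root of the frame count (and, unlike spatial
#' filtering alone, leaves no spatially correlated residue in regional
#' averages).
#'
#' @param series a \linkS4class{VelocityFieldSeries}
#' @return a \linkS4class{VelocityFieldSeries} with identical frames
#' @export
timeAverageSeries <- function(series) {
  v <- series@velocities
  d <- dim(v)
  for (c_i in 1:3) {
    avg <- apply(v[, , , c_i, drop = FALSE], c(1, 2), mean)
    for (k in seq_len(d[3])) v[, , k, c_i] <- avg
  }
  new("VelocityFieldSeries",
    velocities = v, times = series@times, rrInterval = series@rrInterval,
    pixelSpacing = series@pixelSpacing
  )
}

#' Subtract a stationary background velocity map from a subject series
#'
#' Pixel-by-pixel, frame-by-frame, componentwise subtraction of the
#' (smoothed) stationary-phantom velocity maps from the subject velocity
#' maps, removing the background phase errors of the sequence.
#'
#' @param subject a \linkS4class{VelocityFieldSeries}
#' @param stationary a matching \linkS4class{VelocityFieldSeries}
#' @return the corrected \linkS4class{VelocityFieldSeries}
#' @export
subtractBackground <- function(subject, stationary) {
  if (!all(dim(subject@velocities) == dim(stationary@velocities))) {
    stop("subject and stationary series shapes do not match")
  }
  new("VelocityFieldSeries",
    velocities = subject@velocities - stationary@velocities,
    times = subject@times, rrInterval = subject@rrInterval,
    pixelSpacing = subject@pixelSpacing
  )
}
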