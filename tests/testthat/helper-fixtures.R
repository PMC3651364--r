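# Shared fixtures: a compact test acquisition (full-resolution pixels on a
# cropped 64-pixel grid) and small hand-built containers.

testParams <- function(rr = 1000) {
  AcquisitionParams(fov = 90, matrixSize = 64, rrInterval = rr)
}

# A velocity field series with constant per-component values.
constantField <- function(value = c(0, 0, 0), n = 16, nframes = 3,
                          rr = 1000, spacing = 1.40625) {
  v <- array(0, dim = c(n, n, nframes, 3))
  for (i in 1:3) v[, , , i] <- value[i]
  new("VelocityFieldSeries",
    velocities = v, times = seq(0, by = 21, length.out = nframes),
    rrInterval = rr, pixelSpacing = spacing
  )
}

# Circular contours (mm, image-centre origin) for nf frames.
circleContourList <- function(radius, nf = 1, centre = c(0, 0), nv = 72) {
  phis <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  poly <- cbind(centre[1] + radius * sin(phis), centre[2] - radius * cos(phis))
  rep(list(poly), nf)
}

# Geometry of a static annulus on the standard test grid.
annulusGeometry <- function(endoR = 20, epiR = 30, nf = 1, centre = c(0, 0),
                            sliceLevel = "mid", dims = c(64, 64),
                            spacing = 1.40625) {
  computeGeometry(
    circleContourList(endoR, nf, centre), circleContourList(epiR, nf, centre),
    landmark = c(centre[1], centre[2] - (epiR + 2)),
    dims = dims, spacing = spacing, sliceLevel = sliceLevel
  )
}

# A PeakSet built directly from peak/percent prescriptions, for
# reproducibility-table tests.
makePeakSet <- function(direction, tbl, markers = NULL, sliceLevel = "mid") {
  if (is.null(markers)) {
    markers <- new("CardiacPhaseMarkers", tEndSystole = 350,
                   tDiastasisOnset = 550, tAtrialOnset = 800,
                   rrInterval = 1000, atrialFlagged = FALSE)
  }
  tbl$present <- TRUE
  tbl$ttp_ms <- ifelse(tbl$class == "systolic",
                       tbl$ttp_percent / 100 * markers@tEndSystole,
                       markers@tEndSystole + tbl$ttp_percent / 100 *
                         (markers@rrInterval - markers@tEndSystole))
  tbl$ttp_fixed_ms <- vapply(seq_len(nrow(tbl)), function(i) {
    ttpFixedLength(tbl$ttp_percent[i], tbl$class[i])
  }, numeric(1))
  new("PeakSet",
    peaks = tbl[, c("peak", "class", "present", "amplitude", "ttp_ms",
                    "ttp_percent", "ttp_fixed_ms")],
    direction = direction, sliceLevel = sliceLevel, markers = markers,
    eOverA = NA_real_
  )
}

# Sample a model's global curve on the reconstructed phase grid, with
# optional noise, as a VelocityTimeCurve.
modelCurve <- function(model, direction, nPhases = 60, noiseSd = 0) {
  rr <- model@rrInterval
  tt <- (seq_len(nPhases) - 1) * rr / nPhases
  y <- velocityProfile(model, direction, tt)
  if (noiseSd > 0) y <- y + stats::rnorm(length(y), 0, noiseSd)
  velocityTimeCurve(tt, y, rr, direction = direction)
}
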