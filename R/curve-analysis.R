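# Cardiac phase markers, named peak detection, and time-to-peak
# normalization to systolic/diastolic length.

# Cyclic centered moving average (window in frames, odd).
.smoothCyclic <- function(y, window) {
  if (window <= 1) return(y)
  h <- floor(window / 2)
  n <- length(y)
  acc <- numeric(n)
  for (o in -h:h) acc <- acc + y[((seq_len(n) - 1 + o) %% n) + 1]
  acc / (2 * h + 1)
}

# Interior-sense local extrema on a cyclic curve: indices i where
# sign*y[i] >= both cyclic neighbours (plateau points included).
.localExtrema <- function(y, sgn = 1) {
  n <- length(y)
  s <- sgn * y
  prev <- s[c(n, seq_len(n - 1))]
  nxt <- s[c(seq_len(n - 1) + 1, 1)]
  which(s >= prev & s >= nxt)
}

# Log-parabolic sub-sample refinement of an extremum at index i: a
# parabola on log|y| over the three samples centred on the discrete
# extremum, evaluated at its vertex. Exact for Gaussian peaks; for smooth
# compact peaks it recovers most of the amplitude lost to finite
# sampling.
# Returns c(time, amplitude); falls back to the discrete values when the
# neighbourhood is not one-signed and log-concave.
.refineExtremum <- function(times, y, i, rr) {
  n <- length(y)
  disc <- c(times[i], y[i])
  spacing <- if (n > 1) (times[2] - times[1]) else 0
  cyc <- function(k) ((k - 1) %% n) + 1
  fit <- function(half) {
    idx <- cyc((i - half):(i + half))
    yw <- y[idx]
    if (any(yw * y[i] <= 0)) return(NULL)
    x <- (-half):half
    l <- log(abs(yw))
    X <- cbind(1, x, x^2)
    cf <- solve(crossprod(X), crossprod(X, l))
    if (cf[3] >= -1e-12) return(NULL)
    off <- -cf[2] / (2 * cf[3])
    if (abs(off) > 1.25) return(NULL)
    amp <- sign(y[i]) * exp(cf[1] - cf[2]^2 / (4 * cf[3]))
    c((times[i] + off * spacing) %% rr, amp)
  }
  res <- fit(1)
  if (is.null(res)) return(disc)
  # a refinement recovers at most the finite-sampling loss; cap the gain
  if (abs(res[2]) > 1.2 * abs(y[i])) res[2] <- sign(y[i]) * 1.2 * abs(y[i])
  res
}

#' Detect end systole from the global radial velocity curve
#'
#' End systole is the time from the R-wave to the first negative radial
#' peak: after light smoothing, the first local minimum with negative
#' value occurring after the global systolic radial maximum (ties broken
#' to the earliest).
#'
#' @param curve the global radial \linkS4class{VelocityTimeCurve}
#' @param smoothWindow moving-average window in frames (1 disables)
#' @param minDepth minimum depth (cm/s) below zero for a minimum to count,
#'   rejecting noise wiggles at the systolic zero crossing
#' @return end-systole time, ms
#' @export
detectEndSystole <- function(curve, smoothWindow = 3, minDepth = 0.15) {
  y <- .smoothCyclic(curve@values, smoothWindow)
  tt <- curve@times
  imax <- which.max(y)
  mins <- .localExtrema(y, sgn = -1)
  cand <- mins[mins > imax & y[mins] < -abs(minDepth)]
  if (length(cand) == 0) {
    stop("no negative radial minimum after the systolic maximum; ",
         "curve not analyzable")
  }
  tt[min(cand)]
}

#' Detect the cardiac phase markers
#'
#' From the global radial curve and known end systole: the diastasis onset
#' is the first time after the early-diastolic radial peak (D_R) at which
#' |v_R| falls below a fraction (default 25 percent) of |D_R| and stays
#' below for at least `consecutive` phases; the atrial-systole onset is
#' the last local minimum of |v_R| before the atrial-systolic radial peak.
#' When no atrial radial peak is found the atrial onset is imputed at a
#' configurable fraction of diastole and flagged.
#'
#' @param curve the global radial \linkS4class{VelocityTimeCurve}
#' @param tEndSystole end systole, ms (from \code{\link{detectEndSystole}})
#' @param diastasisFraction threshold fraction of |D_R|
#' @param consecutive number of consecutive sub-threshold phases required
#' @param smoothWindow moving-average window in frames
#' @param atrialDefaultFraction fallback atrial onset as a fraction of
#'   diastole when no atrial peak exists
#' @return a \linkS4class{CardiacPhaseMarkers}
#' @export
detectPhaseMarkers <- function(curve, tEndSystole, diastasisFraction = 0.25,
                               consecutive = 2, smoothWindow = 3,
                               atrialDefaultFraction = 0.75) {
  y <- .smoothCyclic(curve@values, smoothWindow)
  tt <- curve@times
  rr <- curve@rrInterval
  n <- length(y)
  spacing <- stats::median(diff(tt))

  afterES <- which(tt > tEndSystole)
  iDR <- afterES[which.min(y[afterES])]
  dAmp <- abs(y[iDR])

  below <- abs(y) < diastasisFraction * dAmp & seq_len(n) > iDR
  iDia <- NA_integer_
  run <- 0
  for (i in which(seq_len(n) > iDR)) {
    run <- if (below[i]) run + 1 else 0
    if (run >= consecutive) { iDia <- i - consecutive + 1; break }
  }
  if (is.na(iDia)) {
    stop("no diastasis found: |v_R| never stays below the threshold")
  }
  tDia <- tt[iDia]

  # atrial-systolic radial peak after diastasis; detrended floor (the
  # early-diastolic recovery flank can reach into early diastasis)
  diaWin <- tt >= tDia & tt <= tDia + 0.4 * (rr - tDia)
  floorAmp <- max(3 * stats::sd(diff(y[diaWin])) / sqrt(2), 1e-8)
  asWin <- which(tt > tDia + 0.3 * (rr - tDia))
  flagged <- FALSE
  if (length(asWin) > 0 && min(y[asWin]) < -floorAmp) {
    iAS <- asWin[which.min(y[asWin])]
    pre <- which(tt > tDia & seq_len(n) < iAS)
    absMins <- intersect(.localExtrema(-abs(y)), pre)
    tAtr <- if (length(absMins) > 0) tt[max(absMins)] else tt[iAS] - 2 * spacing
  } else {
    flagged <- TRUE
    tAtr <- tEndSystole + atrialDefaultFraction * (rr - tEndSystole)
  }
  tAtr <- min(max(tAtr, tDia + spacing / 2), rr - spacing / 2)

  new("CardiacPhaseMarkers",
    tEndSystole = tEndSystole, tDiastasisOnset = tDia, tAtrialOnset = tAtr,
    rrInterval = rr, atrialFlagged = flagged
  )
}

# Pick one extremum in a half-open time window (lo, hi].
# sgn: +1 for maxima, -1 for minima, 0 for either (largest magnitude);
# first: take the earliest qualifying extremum instead of the largest.
# Selection runs on a lightly smoothed copy of the curve (stabler against
# noise-made candidates and the upward selection bias of picking the
# largest of several noisy extrema); the amplitude is then refined on the
# raw curve around the selected sample.
.pickPeak <- function(times, y, rr, lo, hi, sgn, floorAmp,
                      first = FALSE, refine = TRUE, after = -Inf) {
  if (sgn == 0) {
    a <- .pickPeak(times, y, rr, lo, hi, 1, floorAmp, first, refine, after)
    b <- .pickPeak(times, y, rr, lo, hi, -1, floorAmp, first, refine, after)
    if (is.na(a[1])) return(b)
    if (is.na(b[1])) return(a)
    if (first) return(if (a[1] <= b[1]) a else b)
    return(if (abs(a[2]) >= abs(b[2])) a else b)
  }
  ySel <- .smoothCyclic(y, 3)
  ext <- .localExtrema(ySel, sgn)
  cand <- ext[times[ext] > lo & times[ext] <= hi & times[ext] > after &
                sgn * ySel[ext] > floorAmp * 0.8]
  if (length(cand) == 0) return(c(NA_real_, NA_real_))
  i <- if (first) cand[1] else cand[which.max(sgn * ySel[cand])]
  # re-centre on the raw curve within one sample of the selected index
  n <- length(y)
  nb <- ((c(i - 1, i, i + 1) - 1) %% n) + 1
  i <- nb[which.max(sgn * y[nb])]
  if (sgn * y[i] <= max(floorAmp, 0)) return(c(NA_real_, NA_real_))
  if (refine) .refineExtremum(times, y, i, rr) else c(times[i], y[i])
}

#' Detect the named velocity peaks of a curve
#'
#' For longitudinal and radial curves: S (systolic, positive, in (0, end
#' systole]), D (early diastolic, negative, in (end systole, diastasis
#' onset]) and AS (atrial systolic, negative, in (atrial onset, rr]).
#' For circumferential curves: C1 (the first negative local extremum after
#' the R-wave), C2 (the next opposite-sign local extremum within systole;
#' its sign is not enforced apically, where it varies with slice
#' position), and C3 (early diastolic; negative basally, positive
#' apically, not reported for global mid-level curves). A peak is absent
#' when no local extremum exceeds the noise floor (default 3x the standard
#' deviation of the curve within the diastasis window). Discrete extrema
#' are refined by a three-point log-parabolic (Gaussian) interpolation.
#'
#' Times to peak are reported from the R-wave (ms), as a percentage of
#' systolic or diastolic length, and converted to fixed-length ms; the
#' E/A ratio |D|/|AS| is attached for longitudinal and radial curves.
#'
#' @param curve a \linkS4class{VelocityTimeCurve}
#' @param sliceLevel "basal", "mid" or "apical"
#' @param markers a \linkS4class{CardiacPhaseMarkers}
#' @param smoothWindow moving-average window (0 or 1 disables; disable for
#'   exact amplitude recovery)
#' @param refine use sub-sample log-parabolic peak refinement
#' @param noiseFloorFactor multiple of the diastasis-window SD below which
#'   extrema are considered absent
#' @param isGlobal whether this is a global (whole-slice) curve; controls
#'   the mid-level C3 suppression
#' @return a \linkS4class{PeakSet}
#' @export
detectPeaks <- function(curve, sliceLevel, markers, smoothWindow = 0,
                        refine = TRUE, noiseFloorFactor = 3,
                        isGlobal = TRUE) {
  y <- .smoothCyclic(curve@values, max(smoothWindow, 1))
  tt <- curve@times
  rr <- curve@rrInterval
  tES <- markers@tEndSystole
  tDia <- markers@tDiastasisOnset
  tAtr <- markers@tAtrialOnset

  # absent-peak floor from the diastasis-window variability; successive
  # differences detrend the window, since early-diastolic recovery in
  # other directions can outlast the radially-defined diastasis onset
  diaWin <- tt >= tDia & tt < tAtr
  floorAmp <- if (sum(diaWin) >= 3) {
    max(noiseFloorFactor * stats::sd(diff(y[diaWin])) / sqrt(2), 1e-8)
  } else 1e-8

  rows <- list()
  addPeak <- function(name, cls, res) {
    rows[[length(rows) + 1]] <<- data.frame(
      peak = name, class = cls, present = !is.na(res[1]),
      amplitude = res[2], ttp_ms = res[1],
      stringsAsFactors = FALSE
    )
  }

  if (curve@direction %in% c("longitudinal", "radial")) {
    sfx <- if (curve@direction == "longitudinal") "_L" else "_R"
    addPeak(paste0("S", sfx), "systolic",
            .pickPeak(tt, y, rr, 0, tES, 1, floorAmp, refine = refine))
    addPeak(paste0("D", sfx), "diastolic",
            .pickPeak(tt, y, rr, tES, tDia, -1, floorAmp, refine = refine))
    addPeak(paste0("AS", sfx), "diastolic",
            .pickPeak(tt, y, rr, tAtr, rr, -1, floorAmp, refine = refine))
  } else {
    c1 <- .pickPeak(tt, y, rr, 0, tES, -1, floorAmp, first = TRUE,
                    refine = refine)
    addPeak("C1", "systolic", c1)
    c2sgn <- if (sliceLevel == "apical") 0 else 1
    spacing <- stats::median(diff(tt))
    c2 <- .pickPeak(tt, y, rr, 0, tES, c2sgn, floorAmp, first = TRUE,
                    refine = refine,
                    after = if (is.na(c1[1])) -Inf else c1[1] + 0.75 * spacing)
    addPeak("C2", "systolic", c2)
    if (!(sliceLevel == "mid" && isGlobal)) {
      c3sgn <- if (sliceLevel == "apical") 1 else -1
      # the apical C3 peaks within a percent or two of end systole, so
      # the early-diastolic window opens one phase early
      addPeak("C3", "diastolic",
              .pickPeak(tt, y, rr, tES - spacing, tDia, c3sgn, floorAmp,
                        refine = refine))
    }
  }

  peaks <- do.call(rbind, rows)
  peaks$ttp_percent <- NA_real_
  peaks$ttp_fixed_ms <- NA_real_
  for (i in seq_len(nrow(peaks))) {
    if (!peaks$present[i]) next
    pct <- ttpPercent(peaks$ttp_ms[i], peaks$class[i], markers, clamp = TRUE)
    peaks$ttp_percent[i] <- pct
    peaks$ttp_fixed_ms[i] <- ttpFixedLength(pct, peaks$class[i])
  }

  ea <- NA_real_
  if (curve@direction %in% c("longitudinal", "radial")) {
    dA <- peaks$amplitude[grepl("^D", peaks$peak)]
    asA <- peaks$amplitude[grepl("^AS", peaks$peak)]
    if (length(dA) == 1 && length(asA) == 1 &&
        !is.na(dA) && !is.na(asA) && asA != 0) {
      ea <- eOverA(dA, asA)
    }
  }

  new("PeakSet",
    peaks = peaks, direction = curve@direction, sliceLevel = sliceLevel,
    markers = markers, eOverA = ea
  )
}

#' Time to peak as a percentage of systole or diastole
#'
#' Systolic peaks: 100 * t / tEndSystole. Diastolic (including atrial
#' systolic) peaks: 100 * (t - tEndSystole) / (rr - tEndSystole).
#'
#' @param ttpMs time to peak from the R-wave, ms
#' @param class "systolic" or "diastolic"
#' @param markers a \linkS4class{CardiacPhaseMarkers}
#' @param clamp clamp the result into [0, 100] (sub-sample refinement can
#'   place a boundary peak marginally outside its window)
#' @return percentage
#' @export
ttpPercent <- function(ttpMs, class = c("systolic", "diastolic"), markers,
                       clamp = FALSE) {
  class <- match.arg(class)
  if (ttpMs < 0 || ttpMs > markers@rrInterval) {
    stop("time to peak outside [0, rr]")
  }
  pct <- if (class == "systolic") {
    100 * ttpMs / markers@tEndSystole
  } else {
    100 * (ttpMs - markers@tEndSystole) /
      (markers@rrInterval - markers@tEndSystole)
  }
  if (clamp) pct <- min(max(pct, 0), 100)
  pct
}

#' Normalization constants for fixed-length TTP conversion
#'
#' The average lengths of systole (350 ms) and diastole (650 ms) used to
#' express percentage TTP values back in milliseconds on a nominal
#' 1000 ms cycle.
#'
#' @param avgSystole average systolic length, ms
#' @param avgDiastole average diastolic length, ms
#' @return named list
#' @export
normalizationConstants <- function(avgSystole = 350, avgDiastole = 650) {
  if (avgSystole <= 0 || avgDiastole <= 0) {
    stop("normalization constants must be positive")
  }
  list(avgSystole = avgSystole, avgDiastole = avgDiastole)
}

#' Fixed-length TTP in milliseconds
#'
#' Converts a percentage-of-section TTP to milliseconds on the nominal
#' cycle: systolic peaks map to percent/100 * avgSystole; diastolic peaks
#' to avgSystole + percent/100 * avgDiastole. For paired differences the
#' diastolic offset cancels, giving the affine rule
#' delta_ms = delta_percent * avgSystole/100 (systolic, 3.5 ms per
#' percent) or * avgDiastole/100 (diastolic, 6.5 ms per percent).
#'
#' @param percent TTP percentage in [0, 100]
#' @param class "systolic" or "diastolic"
#' @param constants from \code{\link{normalizationConstants}}
#' @return fixed-length TTP, ms (unrounded; printed tables round half away
#'   from zero to one decimal)
#' @examples
#' ttpFixedLength(17.3, "systolic")   # 60.55 -> printed 60.6
#' ttpFixedLength(79.2, "diastolic")  # 864.8
#' @export
ttpFixedLength <- function(percent, class = c("systolic", "diastolic"),
                           constants = normalizationConstants()) {
  class <- match.arg(class)
  if (any(percent < 0 | percent > 100)) {
    stop("percent must lie in [0, 100]")
  }
  if (class == "systolic") {
    percent / 100 * constants$avgSystole
  } else {
    constants$avgSystole + percent / 100 * constants$avgDiastole
  }
}

#' E/A velocity ratio
#'
#' Magnitude ratio of the early-diastolic to the atrial-systolic peak,
#' analogous to the echocardiographic transmitral E/A ratio.
#'
#' @param dAmplitude early-diastolic peak amplitude, cm/s
#' @param asAmplitude atrial-systolic peak amplitude, cm/s
#' @return |D| / |AS|; NA when the atrial peak is absent
#' @export
eOverA <- function(dAmplitude, asAmplitude) {
  if (is.na(asAmplitude) || asAmplitude == 0) return(NA_real_)
  abs(dAmplitude) / abs(asAmplitude)
}

#' @describeIn detectPeaks the peak table of a PeakSet
#' @param x a PeakSet
#' @export
setMethod("peakTable", "PeakSet", function(x) x@peaks)

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet (%s, %s slice):\n", object@direction,
              object@sliceLevel))
  p <- object@peaks
  for (i in seq_len(nrow(p))) {
    if (p$present[i]) {
      cat(sprintf("  %-4s %6.2f cm/s @ %5.1f ms (%5.1f%%, fixed %5.1f ms)\n",
                  p$peak[i], p$amplitude[i], p$ttp_ms[i], p$ttp_percent[i],
                  p$ttp_fixed_ms[i]))
    } else {
      cat(sprintf("  %-4s absent\n", p$peak[i]))
    }
  }
  if (!is.na(object@eOverA)) cat(sprintf("  E/A %.2f\n", object@eOverA))
})
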