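# Default peak prescriptions per slice level.
#
# Amplitudes (cm/s) and peak times as percentages of systolic or diastolic
# length are the healthy-cohort means for basal, mid and apical short-axis
# slices; sd columns are the corresponding between-subject standard
# deviations, used only to calibrate cohort variability. Widths (the
# raised-cosine half-width, ms) are model choices: broad enough that a
# 21 ms acquisition does not alias the peaks, with the first
# circumferential peak kept compact so the biphasic early-systolic pair
# stays temporally resolved.
.pvmPeakDefaults <- function(sliceLevel) {
  tbl <- switch(sliceLevel,
    basal = data.frame(
      direction = rep(c("longitudinal", "radial", "circumferential"), c(3, 3, 3)),
      peak = c("S_L", "D_L", "AS_L", "S_R", "D_R", "AS_R", "C1", "C2", "C3"),
      amplitude = c(6.94, -9.45, -2.62, 2.35, -4.01, -1.41, -2.88, 2.33, -1.58),
      amp_sd = c(1.87, 1.97, 0.99, 0.28, 0.65, 0.41, 1.35, 0.91, 0.52),
      pct = c(17.3, 18.0, 79.2, 34.4, 16.3, 78.0, 12.7, 40.2, 9.3),
      pct_sd = c(1.9, 4.0, 5.3, 4.5, 2.8, 7.1, 2.6, 5.7, 2.5),
      class = c("systolic", "diastolic", "diastolic", "systolic", "diastolic",
                "diastolic", "systolic", "systolic", "diastolic"),
      width = c(120, 110, 105, 160, 85, 105, 95, 105, 100)
    ),
    mid = data.frame(
      direction = rep(c("longitudinal", "radial", "circumferential"), c(3, 3, 2)),
      peak = c("S_L", "D_L", "AS_L", "S_R", "D_R", "AS_R", "C1", "C2"),
      amplitude = c(5.87, -6.50, -1.66, 2.38, -3.61, -1.59, -3.52, 1.40),
      amp_sd = c(1.89, 1.85, 0.67, 0.38, 0.77, 0.43, 1.50, 0.83),
      pct = c(17.1, 20.5, 79.9, 35.3, 21.1, 80.9, 13.9, 42.1),
      pct_sd = c(1.8, 3.7, 4.7, 4.6, 3.1, 4.6, 2.8, 6.1),
      class = c("systolic", "diastolic", "diastolic", "systolic", "diastolic",
                "diastolic", "systolic", "systolic"),
      width = c(120, 110, 105, 160, 85, 105, 95, 105)
    ),
    apical = data.frame(
      direction = rep(c("longitudinal", "radial", "circumferential"), c(3, 3, 3)),
      peak = c("S_L", "D_L", "AS_L", "S_R", "D_R", "AS_R", "C1", "C2", "C3"),
      amplitude = c(4.83, -4.27, -0.81, 2.14, -3.99, -1.57, -3.50, 0.39, 2.09),
      amp_sd = c(1.70, 1.67, 0.29, 0.27, 0.94, 0.45, 1.23, 0.69, 0.72),
      pct = c(14.7, 15.3, 78.3, 32.8, 20.4, 81.6, 13.8, 40.5, 1.4),
      pct_sd = c(2.2, 6.3, 4.7, 6.3, 4.7, 4.4, 1.8, 6.4, 3.3),
      class = c("systolic", "diastolic", "diastolic", "systolic", "diastolic",
                "diastolic", "systolic", "systolic", "diastolic"),
      width = c(120, 110, 105, 160, 85, 105, 95, 105, 100)
    ),
    stop("sliceLevel must be one of 'basal', 'mid', 'apical'")
  )
  tbl
}

# Periodic raised-cosine (Hann) bump train: each bump is
# A * cos^2(pi*d/(2*w)) for wrapped time distance |d| <= w, zero beyond,
# so bumps have compact support (no long tails interfering across peaks)
# and the profile is smooth and periodic across the R-wave.
.bumpTrain <- function(times, bumps, rr) {
  v <- numeric(length(times))
  for (i in seq_len(nrow(bumps))) {
    d <- ((times - bumps$time[i] + rr / 2) %% rr) - rr / 2
    w <- bumps$width[i]
    inside <- abs(d) <= w
    v[inside] <- v[inside] +
      bumps$amplitude[i] * cos(pi * d[inside] / (2 * w))^2
  }
  v
}

# Enforce physiological minimum gaps between consecutive peak times
# within a direction (the later peak is pushed right), keeping the
# biphasic circumferential pair and the end-systolic radial dip
# resolvable under timing jitter.
.enforceSeparations <- function(tbl, tEndSystole, rr) {
  gapAfterES <- c(longitudinal = 25, radial = 110, circumferential = 0)
  for (dd in unique(tbl$direction)) {
    i <- which(tbl$direction == dd)
    i <- i[order(tbl$time[i])]
    for (j in i) {
      if (tbl$class[j] == "diastolic" && !grepl("^(AS|C3)", tbl$peak[j])) {
        tbl$time[j] <- max(tbl$time[j], tEndSystole + gapAfterES[dd])
      }
    }
    if (dd == "circumferential" && all(c("C1", "C2") %in% tbl$peak[i])) {
      i1 <- i[tbl$peak[i] == "C1"]; i2 <- i[tbl$peak[i] == "C2"]
      tbl$time[i2] <- max(tbl$time[i2], tbl$time[i1] + 115)
    }
    tt <- tbl$time[i]
    if (any(diff(tt) <= 0)) tbl$time[i] <- sort(tt) + seq_along(tt) * 1e-6
  }
  tbl$time <- pmin(tbl$time, rr - 20)
  tbl
}

# Solve the width of the designated systolic bump so the profile's cycle
# integral vanishes (periodic motion); clamped to a physiological band.
.balanceWidth <- function(bumps, balancePeak, lower, upper) {
  i <- which(bumps$peak == balancePeak)
  if (length(i) != 1 || abs(bumps$amplitude[i]) < 1e-12) return(bumps)
  other <- sum(bumps$amplitude[-i] * bumps$width[-i])
  w <- -other / bumps$amplitude[i]
  bumps$width[i] <- min(max(w, lower), upper)
  bumps
}

# Adjust bump amplitudes so the realized extrema of the continuous profile
# equal the prescribed peak values (fixed point over the small inter-bump
# overlaps). The search window (+/-50 ms) is narrower than the enforced
# inter-peak gaps, so a neighbouring peak's extremum can never be
# mistaken for the target. Bumps absent from `prescribed` (the
# end-systolic dip) are left untouched.
.solveAmplitudes <- function(bumps, prescribed, rr, nIter = 4) {
  if (nrow(prescribed) == 0) return(bumps)
  tg <- seq(0, rr - 1, by = 1)
  for (iter in seq_len(nIter)) {
    v <- .bumpTrain(tg, bumps, rr)
    for (j in seq_len(nrow(prescribed))) {
      i <- which(bumps$peak == prescribed$peak[j])
      A <- prescribed$amplitude[j]
      if (abs(A) < 1e-12) next
      win <- abs(((tg - prescribed$time[j] + rr / 2) %% rr) - rr / 2) <= 50
      idx <- which(win)
      vv <- sign(A) * v[idx]
      k <- which.max(vv)
      if (k == 1 || k == length(idx)) next  # no interior extremum; skip
      bumps$amplitude[i] <- bumps$amplitude[i] + (A - sign(A) * vv[k])
    }
  }
  bumps
}

#' Build a myocardial motion model
#'
#' Constructs the separable annulus motion model for a slice level. The
#' prescribed peak amplitudes default to the healthy-cohort means for that
#' level, and peak times are placed at the cohort-mean percentage of
#' systole or diastole. The global profiles are periodic raised-cosine
#' bump trains whose bump coefficients are solved so the realized continuous
#' extrema equal the prescribed amplitudes, and whose dominant systolic
#' bump width is solved so each longitudinal/radial profile integrates to
#' approximately zero over the cycle (periodic motion). A small
#' end-systolic radial dip (the first negative radial peak, marking end
#' systole) is always present. The mid-level model has no global C3 peak;
#' the apical C3 is positive, opposite in sign to the basal one
#' (ventricular untwisting).
#'
#' With `seed` and non-zero variability, per-subject variation is drawn as
#' a global amplitude scale times small per-peak amplitude and timing
#' jitters, emulating between-subject spread while preserving the peak
#' pattern.
#'
#' @param sliceLevel "basal", "mid" or "apical"
#' @param amplitudeOverrides named numeric vector (names are peak labels,
#'   e.g. "S_L") of prescribed amplitudes in cm/s replacing the defaults.
#'   Overrides at or beyond the relevant venc are rejected (they would wrap).
#' @param seed integer seed for subject variability (ignored when all
#'   variability is zero)
#' @param params an \linkS4class{AcquisitionParams}; supplies the venc
#'   bounds and the default cycle length
#' @param rrInterval cycle length, ms (defaults to the params value)
#' @param tEndSystole end systole, ms from the R-wave
#' @param suppressAS drop the longitudinal atrial-systolic peak (seen in a
#'   minority of apical acquisitions)
#' @param regionalDepth depth of the cosine angular amplitude modulation
#'   (default 0.3, i.e. +/-30 percent)
#' @param regionalPhase angular position (radians from the anterior
#'   junction) of maximal amplitude; the default places it in the lateral
#'   wall
#' @param transmuralGradient slope g of the endo-to-epi radial amplitude
#'   factor 1 + g*(0.5 - d); the default reproduces the observed
#'   endocardial > mid-wall > epicardial radial ordering
#' @param variability list with `scaleSd` (global amplitude scale),
#'   `peakSd` (per-peak amplitude jitter), `pctSd` (timing jitter as a
#'   multiplier on the per-peak percentage SDs), `tEndSystoleSd` (ms) and
#'   `rrSd` (ms); all zero by default
#' @param pctOverrides named numeric vector of timing percentages (of
#'   systole or diastole, by peak) replacing the defaults; overrides any
#'   jitter
#' @return a \linkS4class{MotionModel}
#' @examples
#' m <- buildMotionModel("basal")
#' modelPeaks(m)
#' @export
buildMotionModel <- function(sliceLevel = c("basal", "mid", "apical"),
                             amplitudeOverrides = NULL, seed = NULL,
                             params = AcquisitionParams(),
                             rrInterval = NULL, tEndSystole = 349,
                             suppressAS = FALSE,
                             regionalDepth = 0.3, regionalPhase = pi / 2,
                             transmuralGradient = 0.45,
                             variability = list(), pctOverrides = NULL) {
  sliceLevel <- match.arg(sliceLevel)
  tbl <- .pvmPeakDefaults(sliceLevel)
  rr <- if (is.null(rrInterval)) params@rrInterval else rrInterval

  vb <- utils::modifyList(
    list(scaleSd = 0, peakSd = 0, pctSd = 0, tEndSystoleSd = 0, rrSd = 0),
    variability
  )

  if (!is.null(amplitudeOverrides)) {
    nm <- names(amplitudeOverrides)
    bad <- setdiff(nm, tbl$peak)
    if (length(bad) > 0) {
      stop("unknown peak name(s) in amplitudeOverrides: ",
           paste(bad, collapse = ", "))
    }
    tbl$amplitude[match(nm, tbl$peak)] <- as.numeric(amplitudeOverrides)
  }
  venc <- ifelse(tbl$direction == "longitudinal",
                 params@vencThroughPlane, params@vencInPlane)
  over <- abs(tbl$amplitude) >= venc
  if (any(over)) {
    stop("prescribed amplitude would exceed venc (phase would wrap) for: ",
         paste(tbl$peak[over], collapse = ", "))
  }

  if (!is.null(seed)) set.seed(seed)
  hasVar <- any(unlist(vb) > 0)
  if (hasVar) {
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    scale <- clamp(stats::rnorm(1, 1, vb$scaleSd), 0.6, 1.4)
    jit <- clamp(stats::rnorm(nrow(tbl), 1, vb$peakSd), 0.75, 1.25)
    tbl$amplitude <- tbl$amplitude * scale * jit
    # timing jitter is shared per cardiac event (the systolic excursion,
    # early filling and atrial contraction move the wall in all
    # directions together), scaled by each peak's own percentage SD
    event <- c(S_L = "S", S_R = "S", D_L = "D", D_R = "D", C3 = "D",
               AS_L = "AS", AS_R = "AS", C1 = "C1", C2 = "C2")[tbl$peak]
    z <- stats::setNames(stats::rnorm(length(unique(event))), unique(event))
    tbl$pct <- clamp(tbl$pct + z[event] * vb$pctSd * tbl$pct_sd,
                     tbl$pct - 2 * tbl$pct_sd, tbl$pct + 2 * tbl$pct_sd)
    tbl$pct <- clamp(tbl$pct, 1, 99)
    tEndSystole <- clamp(stats::rnorm(1, tEndSystole, vb$tEndSystoleSd),
                         tEndSystole - 2.5 * max(vb$tEndSystoleSd, 1e-9),
                         tEndSystole + 2.5 * max(vb$tEndSystoleSd, 1e-9))
    rr <- clamp(stats::rnorm(1, rr, vb$rrSd), 813, 1226)
  }

  if (!is.null(pctOverrides)) {
    nm <- intersect(names(pctOverrides), tbl$peak)
    tbl$pct[match(nm, tbl$peak)] <- as.numeric(pctOverrides[nm])
  }

  if (suppressAS) tbl <- tbl[tbl$peak != "AS_L", ]

  tbl$time <- ifelse(tbl$class == "systolic",
                     tbl$pct / 100 * tEndSystole,
                     tEndSystole + tbl$pct / 100 * (rr - tEndSystole))
  tbl <- .enforceSeparations(tbl, tEndSystole, rr)

  prescribed <- tbl[, c("direction", "peak", "amplitude", "time", "class", "pct")]

  bumps <- tbl[, c("direction", "peak", "amplitude", "time", "width")]
  # end-systolic radial dip: the first negative radial peak
  bumps <- rbind(bumps, data.frame(
    direction = "radial", peak = "ES", amplitude = -1.0,
    time = tEndSystole, width = 40
  ))
  bumps <- bumps[order(match(bumps$direction,
                             c("longitudinal", "radial", "circumferential")),
                       bumps$time), ]

  solveDir <- function(bumps, dir, balancePeak, lower, upper) {
    sel <- bumps$direction == dir
    b <- bumps[sel, ]
    pres <- prescribed[prescribed$direction == dir, ]
    # the balanced systolic bump must not wrap across the R-wave into
    # the atrial-systolic support (short cycles crowd the peaks)
    iB <- which(b$peak == balancePeak)
    iAS <- grep("^AS", b$peak)
    if (length(iB) == 1 && length(iAS) == 1) {
      upper <- min(upper, rr + b$time[iB] - b$time[iAS] - 20)
    }
    for (pass in 1:2) {
      b <- .balanceWidth(b, balancePeak, lower, upper)
      b <- .solveAmplitudes(b, pres, rr)
    }
    bumps[sel, ] <- b
    bumps
  }
  bumps <- solveDir(bumps, "longitudinal", "S_L", 90, 200)
  bumps <- solveDir(bumps, "radial", "S_R", 100, 220)
  selC <- bumps$direction == "circumferential"
  bumps[selC, ] <- .solveAmplitudes(bumps[selC, ],
                                    prescribed[prescribed$direction ==
                                                 "circumferential", ], rr)

  # record the realized continuous-curve extremum times as ground truth
  # (bump overlap can shift an extremum slightly off its bump centre)
  tg <- seq(0, rr - 1, by = 0.5)
  for (j in seq_len(nrow(prescribed))) {
    if (abs(prescribed$amplitude[j]) < 1e-12) next
    b <- bumps[bumps$direction == prescribed$direction[j], ]
    v <- .bumpTrain(tg, b, rr)
    win <- which(abs(((tg - prescribed$time[j] + rr / 2) %% rr) - rr / 2) <= 50)
    k <- win[which.max(sign(prescribed$amplitude[j]) * v[win])]
    prescribed$time[j] <- tg[k]
  }
  prescribed$pct <- ifelse(
    prescribed$class == "systolic",
    100 * prescribed$time / tEndSystole,
    100 * (prescribed$time - tEndSystole) / (rr - tEndSystole)
  )

  # ground-truth markers derived from the radial prescription: the 25%
  # crossing of a raised-cosine bump sits 2w/3 after its centre, and the
  # atrial bump foot about 0.85w before its centre
  tDR <- prescribed$time[prescribed$peak == "D_R"]
  wDR <- bumps$width[bumps$peak == "D_R"]
  tAS <- prescribed$time[prescribed$peak == "AS_R"]
  wAS <- bumps$width[bumps$peak == "AS_R"]
  tDia <- tDR + 2 * wDR / 3
  tAtr <- max(tAS - 0.85 * wAS, tDia + 1)
  markers <- c(tEndSystole = tEndSystole, tDiastasisOnset = tDia,
               tAtrialOnset = tAtr)

  new("MotionModel",
    sliceLevel = sliceLevel, bumps = bumps, prescribed = prescribed,
    markers = markers,
    regional = list(depth = regionalDepth, phase = regionalPhase),
    transmuralGradient = transmuralGradient, rrInterval = rr
  )
}

#' Evaluate the motion model velocity
#'
#' Evaluates v(t, theta, d) = f(t) * m(theta) * g(d) for one direction.
#' With `theta = NULL` the unmodulated global profile f(t) is returned.
#' The transmural factor g applies to the radial direction only.
#'
#' @param model a \linkS4class{MotionModel}
#' @param direction "longitudinal", "radial" or "circumferential"
#' @param times ms from the R-wave
#' @param theta angular coordinate(s), radians from the anterior junction
#' @param depth transmural depth(s) in [0, 1]
#' @return velocity in cm/s, same length as `times` (recycled against
#'   theta/depth)
#' @export
setMethod("velocityProfile", "MotionModel",
  function(model, direction, times, theta = NULL, depth = NULL) {
    b <- model@bumps[model@bumps$direction == direction, ]
    f <- .bumpTrain(times, b, model@rrInterval)
    if (!is.null(theta)) {
      f <- f * (1 + model@regional$depth *
                  cos(theta - model@regional$phase))
    }
    if (!is.null(depth) && direction == "radial") {
      f <- f * (1 + model@transmuralGradient * (0.5 - depth))
    }
    f
  }
)

#' Prescribed (ground-truth) peaks of a motion model
#'
#' @param model a \linkS4class{MotionModel}
#' @return data.frame with direction, peak, amplitude (cm/s), time (ms),
#'   peak class and the percentage-of-section timing
#' @export
modelPeaks <- function(model) model@prescribed

#' Ground-truth cardiac phase markers of a motion model
#'
#' @param model a \linkS4class{MotionModel}
#' @return a \linkS4class{CardiacPhaseMarkers}
#' @export
modelMarkers <- function(model) {
  new("CardiacPhaseMarkers",
    tEndSystole = unname(model@markers["tEndSystole"]),
    tDiastasisOnset = unname(model@markers["tDiastasisOnset"]),
    tAtrialOnset = unname(model@markers["tAtrialOnset"]),
    rrInterval = model@rrInterval, atrialFlagged = FALSE
  )
}

#' @describeIn buildMotionModel slice level of a motion model
#' @param x a MotionModel
#' @export
setMethod("sliceLevel", "MotionModel", function(x) x@sliceLevel)

#' @describeIn buildMotionModel cycle length of a motion model, ms
#' @export
setMethod("rrInterval", "MotionModel", function(x) x@rrInterval)

setMethod("show", "MotionModel", function(object) {
  cat(sprintf("MotionModel (%s slice, RR %.0f ms)\n",
              object@sliceLevel, object@rrInterval))
  cat(sprintf("  end systole %.0f ms; %d prescribed peaks\n",
              object@markers["tEndSystole"], nrow(object@prescribed)))
  p <- object@prescribed
  cat(sprintf("  %s: %.2f cm/s @ %.0f ms\n", p$peak, p$amplitude, p$time),
      sep = "")
})
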