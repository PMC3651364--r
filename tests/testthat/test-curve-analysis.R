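hann <- function(t, A, t0, w) {
  d <- abs(t - t0)
  ifelse(d <= w, A * cos(pi * d / (2 * w))^2, 0)
}

test_that("end systole is the first negative radial minimum", {
  tt <- (0:59) * 1000 / 60
  y <- hann(tt, 2.4, 120, 160) + hann(tt, -1, 350, 40) +
    hann(tt, -4, 460, 85) + hann(tt, -1.4, 860, 95)
  cu <- velocityTimeCurve(tt, y, 1000)
  expect_lt(abs(detectEndSystole(cu) - 350), 1000 / 60)
  # a pure sine has its only negative minimum at 3rr/4
  cu2 <- velocityTimeCurve(tt, sin(2 * pi * tt / 1000), 1000)
  expect_equal(detectEndSystole(cu2), 750, tolerance = 1000 / 60)
  # a never-negative curve is not analyzable
  cu3 <- velocityTimeCurve(tt, 1 + sin(2 * pi * tt / 1000)^2, 1000)
  expect_error(detectEndSystole(cu3), "not analyzable")
})

test_that("phase markers locate diastasis and atrial onset", {
  tt <- (0:59) * 1000 / 60
  # flat zero diastasis from 500 to 800 ms, atrial bump at 870
  y <- hann(tt, 2.4, 120, 160) + hann(tt, -1, 350, 40) +
    hann(tt, -4, 440, 60) + hann(tt, -1.5, 870, 60)
  cu <- velocityTimeCurve(tt, y, 1000)
  mk <- detectPhaseMarkers(cu, 350)
  expect_lt(abs(mk@tDiastasisOnset - 500), 45)
  expect_lt(abs(mk@tAtrialOnset - 800), 45)
  expect_false(mk@atrialFlagged)
  # without an atrial bump the onset is imputed and flagged
  y2 <- hann(tt, 2.4, 120, 160) + hann(tt, -1, 350, 40) +
    hann(tt, -4, 440, 60)
  mk2 <- detectPhaseMarkers(velocityTimeCurve(tt, y2, 1000), 350)
  expect_true(mk2@atrialFlagged)
})

test_that("markers scale with a uniform time-scaling of the curve", {
  for (fac in c(0.85, 1.3)) {
    rr <- 1000 * fac
    tt <- (0:59) * rr / 60
    y <- hann(tt, 2.4, 120 * fac, 160 * fac) +
      hann(tt, -1, 350 * fac, 40 * fac) +
      hann(tt, -4, 460 * fac, 85 * fac) +
      hann(tt, -1.4, 860 * fac, 95 * fac)
    cu <- velocityTimeCurve(tt, y, rr)
    tES <- detectEndSystole(cu)
    mk <- detectPhaseMarkers(cu, tES)
    expect_lt(abs(tES - 350 * fac), rr / 60 + 1)
    expect_lt(abs(mk@tDiastasisOnset / fac - 520), 60)
    expect_lt(abs(mk@tAtrialOnset / fac - 790), 60)
  }
})

test_that("markers are strictly ordered for default synthetic subjects", {
  vb <- list(scaleSd = 0.15, peakSd = 0.10, pctSd = 1,
             tEndSystoleSd = 38, rrSd = 121)
  for (seed in 1:6) {
    m <- buildMotionModel("mid", seed = 300 + seed, variability = vb)
    set.seed(seed)
    cu <- modelCurve(m, "radial", noiseSd = 0.016)
    tES <- detectEndSystole(cu)
    mk <- detectPhaseMarkers(cu, tES)
    expect_true(0 < mk@tEndSystole &&
                  mk@tEndSystole < mk@tDiastasisOnset &&
                  mk@tDiastasisOnset < mk@tAtrialOnset &&
                  mk@tAtrialOnset < mk@rrInterval)
  }
})

stdMarkers <- new("CardiacPhaseMarkers", tEndSystole = 350,
                  tDiastasisOnset = 550, tAtrialOnset = 800,
                  rrInterval = 1000, atrialFlagged = FALSE)

test_that("named peaks are recovered from constructed curves", {
  tt <- (0:59) * 1000 / 60
  y <- hann(tt, 5, 60, 90) + hann(tt, -7, 460, 85) + hann(tt, -2, 870, 95)
  cu <- velocityTimeCurve(tt, y, 1000, direction = "longitudinal")
  ps <- detectPeaks(cu, "mid", stdMarkers, smoothWindow = 0)
  pt <- peakTable(ps)
  expect_equal(pt$amplitude[pt$peak == "S_L"], 5, tolerance = 0.03)
  expect_lt(abs(pt$ttp_ms[pt$peak == "S_L"] - 60), 1000 / 60)
  expect_equal(pt$amplitude[pt$peak == "D_L"], -7, tolerance = 0.03)
  expect_lt(abs(pt$ttp_ms[pt$peak == "D_L"] - 460), 1000 / 60)
  expect_equal(pt$amplitude[pt$peak == "AS_L"], -2, tolerance = 0.03)
  expect_lt(abs(pt$ttp_ms[pt$peak == "AS_L"] - 870), 1000 / 60)
  expect_equal(ps@eOverA, 3.5, tolerance = 0.1)
})

test_that("absent peaks are reported as absent, not errors", {
  tt <- (0:59) * 1000 / 60
  # apical longitudinal with atrial systole suppressed
  y <- hann(tt, 4.8, 52, 90) + hann(tt, -4.3, 455, 85)
  cu <- velocityTimeCurve(tt, y, 1000, direction = "longitudinal")
  ps <- detectPeaks(cu, "apical", stdMarkers, smoothWindow = 0)
  pt <- peakTable(ps)
  expect_false(pt$present[pt$peak == "AS_L"])
  expect_true(pt$present[pt$peak == "S_L"])
  expect_true(is.na(ps@eOverA))
  # an all-zero curve has no peaks at all
  ps0 <- detectPeaks(velocityTimeCurve(tt, rep(0, 60), 1000,
                                       direction = "radial"),
                     "mid", stdMarkers, smoothWindow = 0)
  expect_false(any(peakTable(ps0)$present))
})

test_that("circumferential peaks follow the biphasic pattern per level", {
  tt <- (0:59) * 1000 / 60
  yB <- hann(tt, -2.9, 45, 85) + hann(tt, 2.3, 160, 105) +
    hann(tt, -1.6, 410, 100)
  cuB <- velocityTimeCurve(tt, yB, 1000, direction = "circumferential")
  ptB <- peakTable(detectPeaks(cuB, "basal", stdMarkers, smoothWindow = 0))
  expect_equal(ptB$amplitude[ptB$peak == "C1"], -2.9, tolerance = 0.05)
  expect_equal(ptB$amplitude[ptB$peak == "C2"], 2.3, tolerance = 0.05)
  expect_equal(ptB$amplitude[ptB$peak == "C3"], -1.6, tolerance = 0.05)
  # apical: C3 positive; C2 sign unconstrained (here negative)
  yA <- hann(tt, -3.5, 48, 85) + hann(tt, -0.4, 165, 60) +
    hann(tt, 2.1, 420, 100)
  cuA <- velocityTimeCurve(tt, yA, 1000, direction = "circumferential")
  ptA <- peakTable(detectPeaks(cuA, "apical", stdMarkers, smoothWindow = 0))
  expect_equal(ptA$amplitude[ptA$peak == "C2"], -0.4, tolerance = 0.1)
  expect_gt(ptA$amplitude[ptA$peak == "C3"], 0)
  # mid-level global curves carry no C3
  ptM <- peakTable(detectPeaks(cuB, "mid", stdMarkers, smoothWindow = 0))
  expect_false("C3" %in% ptM$peak)
  # recovered C3 signs are opposite between base and apex (wringing)
  expect_lt(ptB$amplitude[ptB$peak == "C3"] * ptA$amplitude[ptA$peak == "C3"],
            0)
})

test_that("peak recovery holds over 100 random synthetic curves", {
  vb <- list(scaleSd = 0.15, peakSd = 0.10, pctSd = 1,
             tEndSystoleSd = 38, rrSd = 121)
  checked <- 0
  s <- 0
  while (checked < 100) {
    s <- s + 1
    lvl <- c("basal", "mid", "apical")[(s %% 3) + 1]
    m <- buildMotionModel(lvl, seed = 2000 + s, variability = vb)
    curves <- lapply(c("radial", "longitudinal", "circumferential"),
                     function(d) modelCurve(m, d))
    tES <- detectEndSystole(curves[[1]])
    mk <- detectPhaseMarkers(curves[[1]], tES)
    gt <- modelPeaks(m)
    for (cu in curves) {
      pt <- peakTable(detectPeaks(cu, lvl, mk, smoothWindow = 0))
      for (i in seq_len(nrow(pt))) {
        g <- gt[gt$peak == pt$peak[i], ]
        if (nrow(g) != 1) next
        expect_true(pt$present[i])
        expect_lt(abs(pt$amplitude[i] / g$amplitude - 1), 0.05)
        expect_lt(abs(pt$ttp_ms[i] - g$time), m@rrInterval / 60)
        checked <- checked + 1
      }
    }
  }
  expect_gte(checked, 100)
})

test_that("TTP percentages follow the systole/diastole definitions", {
  expect_equal(ttpPercent(350, "systolic", stdMarkers), 100)
  expect_equal(ttpPercent(1000, "diastolic", stdMarkers), 100)
  expect_equal(ttpPercent(467, "diastolic", stdMarkers), 18)
  expect_equal(ttpPercent(175, "systolic", stdMarkers), 50)
  expect_error(ttpPercent(-1, "systolic", stdMarkers), "outside")
  expect_error(ttpPercent(1001, "diastolic", stdMarkers), "outside")
  # invariant under uniform time scaling of curve and markers
  for (fac in c(0.5, 0.8, 1.4, 2)) {
    mk <- new("CardiacPhaseMarkers", tEndSystole = 350 * fac,
              tDiastasisOnset = 550 * fac, tAtrialOnset = 800 * fac,
              rrInterval = 1000 * fac, atrialFlagged = FALSE)
    expect_equal(ttpPercent(467 * fac, "diastolic", mk), 18,
                 tolerance = 1e-9)
    expect_equal(ttpPercent(120 * fac, "systolic", mk),
                 ttpPercent(120, "systolic", stdMarkers), tolerance = 1e-9)
  }
})

test_that("fixed-length TTP conversion matches the printed normalization", {
  rh <- spiralPVM:::roundHalfAway
  expect_equal(rh(ttpFixedLength(17.3, "systolic")), 60.6)
  expect_equal(rh(ttpFixedLength(79.2, "diastolic")), 864.8)
  expect_equal(ttpFixedLength(0, "systolic"), 0)
  expect_error(ttpFixedLength(101, "systolic"), "0, 100")
  # affine: differences map through 3.5 (systolic) or 6.5 (diastolic)
  for (pair in list(c(10, 35), c(2.5, 97))) {
    dS <- ttpFixedLength(pair[2], "systolic") -
      ttpFixedLength(pair[1], "systolic")
    expect_equal(dS, diff(pair) * 3.5, tolerance = 1e-12)
    dD <- ttpFixedLength(pair[2], "diastolic") -
      ttpFixedLength(pair[1], "diastolic")
    expect_equal(dD, diff(pair) * 6.5, tolerance = 1e-12)
  }
  expect_error(normalizationConstants(-1, 650), "positive")
})

test_that("E/A is the magnitude ratio of early to atrial peaks", {
  expect_equal(eOverA(-3, -1.5), 2)
  expect_equal(eOverA(-2.2, -2.2), 1)
  expect_true(is.na(eOverA(-3, NA)))
  # a subject prescribed D_R = -4, AS_R = -1.6 recovers E/A = 2.5
  tt <- (0:59) * 1000 / 60
  y <- hann(tt, 2.35, 120, 160) + hann(tt, -1, 350, 40) +
    hann(tt, -4, 460, 85) + hann(tt, -1.6, 860, 95)
  cu <- velocityTimeCurve(tt, y, 1000, direction = "radial")
  ps <- detectPeaks(cu, "mid", stdMarkers, smoothWindow = 0)
  expect_equal(ps@eOverA, 2.5, tolerance = 0.05)
})
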