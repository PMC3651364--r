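# End-to-end orchestration: simulate -> reconstruct -> analyze -> report.

#' Default cohort configuration
#'
#' The study conditions of the synthetic cohort: ten healthy subjects,
#' mid-ventricular short-axis slice, the default acquisition protocol on a
#' 64-pixel sub-grid (90 mm cropped field of view at the acquired 1.4 mm
#' pixel spacing), phase noise of 0.05 rad, smooth polynomial background
#' phase, and between-subject variability calibrated to the healthy-cohort
#' spread (global amplitude scale SD 0.15, per-peak jitter SD 0.10, timing
#' jitter at the cohort percentage SDs, end-systole SD 38 ms, RR SD
#' 121 ms).
#'
#' @param nSubjects number of subjects
#' @param sliceLevel slice level for the cohort
#' @param seed master seed; all per-subject seeds derive from it
#' @param visits 1 or 2 (two visits enable reproducibility analysis)
#' @param gridSize pixel grid size (cropped field of view)
#' @param noiseSd phase noise SD, radians
#' @param backgroundScale multiplier on the background polynomial spread
#'   (0 disables the background)
#' @param rrDay2DeltaRange uniform range (ms) of the day-2 RR change
#' @param outDir optional output directory for CSV/JSON reports
#' @return a configuration list for \code{\link{runCohort}}
#' @export
defaultCohortConfig <- function(nSubjects = 10, sliceLevel = "mid", seed = 1,
                                visits = 1, gridSize = 64, noiseSd = 0.05,
                                backgroundScale = 1,
                                rrDay2DeltaRange = c(-200, 200),
                                outDir = NULL) {
  list(
    nSubjects = nSubjects, sliceLevel = sliceLevel, seed = seed,
    visits = visits, gridSize = gridSize, noiseSd = noiseSd,
    backgroundScale = backgroundScale,
    rrDay2DeltaRange = rrDay2DeltaRange,
    endoRadius = 20, epiRadius = 30,
    fov = 90, matrixSize = 64,
    variability = list(scaleSd = 0.15, peakSd = 0.10, pctSd = 1,
                       tEndSystoleSd = 38, rrSd = 121),
    detection = list(smoothWindow = 0, refine = TRUE),
    colourDirections = "longitudinal",
    template = list(systole = 350, earlyDiastole = 150, diastasis = 300,
                    atrialSystole = 200, nPoints = 60),
    outDir = outDir
  )
}

#' Load a cohort configuration from YAML
#'
#' Reads a YAML key-value file and merges it over the defaults.
#'
#' @param path YAML file path
#' @return configuration list
#' @export
readCohortConfig <- function(path) {
  utils::modifyList(defaultCohortConfig(), yaml::read_yaml(path))
}

#' Rebuild a motion model at a different cycle length
#'
#' Keeps the subject's prescribed amplitudes, end-systolic time and
#' section-relative peak timing fractions, and re-places the peaks on the
#' new cycle (systole length is preserved; diastole stretches). Optionally
#' applies a small day-to-day amplitude jitter. Used for second-visit
#' simulation at a changed heart rate.
#'
#' @param model a \linkS4class{MotionModel}
#' @param rrInterval new cycle length, ms
#' @param amplitudeJitterSd SD of a multiplicative per-peak day effect
#' @param seed seed for the jitter
#' @return a \linkS4class{MotionModel}
#' @export
rescaleModel <- function(model, rrInterval, amplitudeJitterSd = 0,
                         seed = NULL) {
  pres <- model@prescribed
  amp <- pres$amplitude
  if (amplitudeJitterSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    amp <- amp * pmin(pmax(stats::rnorm(length(amp), 1, amplitudeJitterSd),
                           0.8), 1.2)
  }
  ov <- stats::setNames(amp, pres$peak)
  pct <- stats::setNames(pres$pct, pres$peak)
  suppressAS <- model@sliceLevel == "apical" &&
    !("AS_L" %in% pres$peak)
  buildMotionModel(
    sliceLevel = model@sliceLevel, amplitudeOverrides = ov,
    rrInterval = rrInterval,
    tEndSystole = unname(model@markers["tEndSystole"]),
    suppressAS = suppressAS,
    regionalDepth = model@regional$depth,
    regionalPhase = model@regional$phase,
    transmuralGradient = model@transmuralGradient,
    pctOverrides = pct
  )
}

#' Simulate one synthetic subject acquisition
#'
#' Builds the subject's motion model (with cohort variability), renders
#' the ground-truth velocity frames at the acquired temporal resolution,
#' encodes the four phase sets with background phase and noise, and
#' generates the matching stationary-phantom series.
#'
#' @param config configuration list (see \code{\link{defaultCohortConfig}})
#' @param subject subject index
#' @param visit visit index (1 or 2)
#' @param model optional pre-built \linkS4class{MotionModel} (visit 2 uses
#'   the visit-1 model rescaled to a new RR)
#' @return list with `model`, `params`, `render`, `encoded`, `stationary`,
#'   `backgroundCoeffs`
#' @export
simulateSubject <- function(config, subject, visit = 1, model = NULL) {
  baseSeed <- config$seed * 10000 + subject * 10
  if (is.null(model)) {
    model <- buildMotionModel(
      config$sliceLevel, seed = baseSeed,
      variability = config$variability
    )
  }
  params <- AcquisitionParams(fov = config$fov,
                              matrixSize = config$matrixSize,
                              rrInterval = model@rrInterval)
  rend <- renderVelocityFrames(model, params, gridSize = config$gridSize,
                               endoRadius = config$endoRadius,
                               epiRadius = config$epiRadius)
  bg <- if (config$backgroundScale > 0) {
    randomBackgroundCoeffs(baseSeed + visit, scale = config$backgroundScale)
  } else NULL
  enc <- encodePhases(rend$velocity, params, bg,
                      noiseSd = config$noiseSd, seed = baseSeed + visit + 1,
                      mask = rend$mask)
  stat <- generateStationarySeries(params, gridSize = config$gridSize,
                                   times = rend$velocity@times,
                                   backgroundCoeffs = bg,
                                   noiseSd = config$noiseSd,
                                   seed = baseSeed + visit + 5)
  list(model = model, params = params, render = rend, encoded = enc,
       stationary = stat, backgroundCoeffs = bg)
}

#' Reconstruct and analyze one simulated subject
#'
#' Runs the image-domain reconstruction chain (phase differencing,
#' stationary-map smoothing and subtraction, retrospective-gating
#' interpolation to 60 phases), rebuilds the geometry on the reconstructed
#' phase grid, decomposes velocities into the cylindrical system, and
#' quantifies global curves, phase markers, peaks, transmural layer curves
#' and the 24-segment normalized curves.
#'
#' @param sim result of \code{\link{simulateSubject}}
#' @param config configuration list
#' @return list with `curves` (global, per direction), `markers`, `peaks`
#'   (list of \linkS4class{PeakSet} per direction), `layerCurves`,
#'   `segment24`, `cycleMeans`, `geometry`
#' @export
analyzeSubject <- function(sim, config) {
  det <- config$detection
  v <- phaseDifferenceToVelocity(sim$encoded)
  # the stationary phantom's background phase is static: time-average its
  # maps (noise down by sqrt(frames)) before a light median smoothing
  kernel <- if (is.null(config$stationaryKernel)) 3 else {
    config$stationaryKernel
  }
  vStat <- smoothBackgroundMap(
    timeAverageSeries(phaseDifferenceToVelocity(sim$stationary)), kernel)
  vCorr <- subtractBackground(v, vStat)
  v60 <- retroGateInterpolate(vCorr, 60)

  cont <- annulusContours(sim$model, v60@times,
                          config$endoRadius, config$epiRadius)
  contA <- annulusContours(sim$model, vCorr@times,
                           config$endoRadius, config$epiRadius)
  # conservative contouring: pull both borders one pixel into the wall so
  # region averages are not diluted by partial-volume pixels at the
  # moving myocardial boundary
  margin <- if (is.null(config$contourMargin)) {
    v60@pixelSpacing
  } else {
    config$contourMargin
  }
  shrink <- function(polys, delta) {
    lapply(polys, function(p) {
      ctr <- colMeans(p)
      dx <- p[, 1] - ctr[1]; dy <- p[, 2] - ctr[2]
      r <- sqrt(dx^2 + dy^2)
      f <- pmax(r + delta, 0.1) / r
      cbind(ctr[1] + dx * f, ctr[2] + dy * f)
    })
  }
  geom <- computeGeometry(shrink(cont$endo, margin),
                          shrink(cont$epi, -margin), cont$landmark,
                          dims = dim(v60@velocities)[1:2],
                          spacing = v60@pixelSpacing,
                          sliceLevel = sim$model@sliceLevel)
  cyl <- toCylindrical(v60, geom)
  segAha <- assignSegments(geom, "aha")
  seg24 <- assignSegments(geom, "equal24")

  dirs <- c("longitudinal", "radial", "circumferential")
  curves <- lapply(dirs, function(d) regionAverage(cyl, segAha, "global", d))
  names(curves) <- dirs

  tES <- detectEndSystole(curves$radial)
  markers <- detectPhaseMarkers(curves$radial, tES)
  # peak quantification runs on the acquired-resolution region curves:
  # the retrospective 60-phase interpolation (used for markers,
  # normalization and the cohort maps) attenuates narrow extrema, and
  # the corrected acquired-time series is available upstream of it
  geomA <- computeGeometry(shrink(contA$endo, margin),
                           shrink(contA$epi, -margin), contA$landmark,
                           dims = dim(vCorr@velocities)[1:2],
                           spacing = vCorr@pixelSpacing,
                           sliceLevel = sim$model@sliceLevel)
  cylA <- toCylindrical(vCorr, geomA)
  segA <- assignSegments(geomA, "aha")
  peaks <- lapply(dirs, function(d) {
    cu <- regionAverage(cylA, segA, "global", d)
    detectPeaks(cu, sim$model@sliceLevel, markers,
                smoothWindow = det$smoothWindow, refine = det$refine)
  })
  names(peaks) <- dirs

  layers <- c("endo", "mid-wall", "epi")
  layerCurves <- lapply(layers, function(l) {
    regionAverage(cyl, segAha, l, "radial")
  })
  names(layerCurves) <- layers

  tmpl <- do.call(phaseTemplate, config$template)
  seg24Curves <- lapply(config$colourDirections, function(d) {
    lapply(seq_len(24), function(s) {
      cu <- regionAverage(cyl, seg24, sprintf("seg%02d", s), d)
      normalizeCurve(cu, markers, tmpl)
    })
  })
  names(seg24Curves) <- config$colourDirections

  cycleMeans <- vapply(curves, function(cu) mean(cu@values), numeric(1))

  list(curves = curves, markers = markers, peaks = peaks,
       layerCurves = layerCurves, segment24 = seg24Curves,
       cycleMeans = cycleMeans, geometry = geom, template = tmpl)
}

#' Run a full synthetic cohort
#'
#' Generates `nSubjects` synthetic subjects (two visits when configured,
#' the second at a changed heart rate with identical section-relative
#' timing), runs every analysis stage, and assembles cohort outputs:
#' per-subject peak tables, cycle means, group-averaged normalized curves,
#' 24-segment colour grids, and (with two visits) the inter-study
#' reproducibility table. Re-running with the same configuration is
#' bit-identical. With `outDir` set, curve CSVs, peak and reproducibility
#' tables, colour grids and a JSON run log are written.
#'
#' @param config configuration list from \code{\link{defaultCohortConfig}}
#'   or \code{\link{readCohortConfig}}
#' @return list with `subjects`, `peaks` (per visit), `cycleMeans`,
#'   `colourGrids`, `reproducibility` (NULL for one visit), `config`
#' @export
runCohort <- function(config = defaultCohortConfig()) {
  stageFail <- function(stage, subject, e) {
    stop(sprintf("stage '%s' failed for subject %d: %s",
                 stage, subject, conditionMessage(e)), call. = FALSE)
  }
  subjects <- vector("list", config$nSubjects)
  peaksByVisit <- list()
  cycleMeans <- list()
  for (s in seq_len(config$nSubjects)) {
    subj <- list()
    for (visit in seq_len(config$visits)) {
      model <- NULL
      if (visit == 2) {
        set.seed(config$seed * 10000 + s * 10 + 7)
        delta <- if (!is.null(config$rrDay2Fixed)) {
          # fixed-magnitude heart-rate change with random sign
          sample(c(-1, 1), 1) * config$rrDay2Fixed
        } else {
          stats::runif(1, config$rrDay2DeltaRange[1],
                       config$rrDay2DeltaRange[2])
        }
        rr2 <- min(max(subj[[1]]$sim$model@rrInterval + delta, 700), 1400)
        model <- rescaleModel(subj[[1]]$sim$model, rr2)
      }
      sim <- tryCatch(simulateSubject(config, s, visit, model),
                      error = function(e) stageFail("simulate", s, e))
      ana <- tryCatch(analyzeSubject(sim, config),
                      error = function(e) stageFail("analyze", s, e))
      subj[[visit]] <- list(sim = sim, analysis = ana)
      vKey <- paste0("visit", visit)
      peaksByVisit[[vKey]][[sprintf("subject%02d", s)]] <- ana$peaks
      cycleMeans[[vKey]][[s]] <- ana$cycleMeans
    }
    subjects[[s]] <- subj
  }

  # cohort colour grids: group-average the normalized segment curves
  tmpl <- do.call(phaseTemplate, config$template)
  colourGrids <- lapply(config$colourDirections, function(d) {
    segMeans <- lapply(seq_len(24), function(sg) {
      groupAverage(lapply(subjects, function(subj) {
        subj[[1]]$analysis$segment24[[d]][[sg]]
      }))$mean
    })
    buildColourGrid(segMeans, d, config$sliceLevel, tmpl)
  })
  names(colourGrids) <- config$colourDirections

  repro <- NULL
  if (config$visits >= 2) {
    repro <- reproducibilityTable(peaksByVisit$visit1, peaksByVisit$visit2)
  }

  cm <- lapply(cycleMeans, function(v) do.call(rbind, v))
  out <- list(subjects = subjects, peaks = peaksByVisit, cycleMeans = cm,
              colourGrids = colourGrids, reproducibility = repro,
              config = config)
  if (!is.null(config$outDir)) writeCohortOutputs(out, config$outDir)
  out
}
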