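#' @useDynLib spiralPVM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Acquisition parameters for a spiral phase velocity mapping sequence
#'
#' Holds all sequence constants: the through-plane and in-plane velocity
#' sensitivities (venc, the velocity producing a phase shift of pi), the
#' interleaved spiral geometry, matrix and field of view, the acquired
#' temporal resolution, the number of retrospectively reconstructed cardiac
#' phases, and the respiratory navigator acceptance window.
#'
#' @slot vencThroughPlane velocity sensitivity for the slice-normal
#'   (longitudinal) direction, cm/s
#' @slot vencInPlane velocity sensitivity for the two in-plane directions, cm/s
#' @slot nInterleaves number of spiral interleaves covering k-space
#' @slot spiralReadoutDuration duration of one spiral readout, ms
#' @slot temporalResolution acquired frame spacing, ms
#' @slot fov field of view, mm
#' @slot matrixSize reconstructed matrix size (square, even)
#' @slot nReconstructedPhases number of equally spaced cardiac phases after
#'   retrospective interpolation
#' @slot sliceThickness slice thickness, mm
#' @slot navigatorWindow diaphragmatic navigator acceptance window, mm
#' @slot rrInterval cardiac cycle length, ms
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(
    vencThroughPlane = "numeric",
    vencInPlane = "numeric",
    nInterleaves = "numeric",
    spiralReadoutDuration = "numeric",
    temporalResolution = "numeric",
    fov = "numeric",
    matrixSize = "numeric",
    nReconstructedPhases = "numeric",
    sliceThickness = "numeric",
    navigatorWindow = "numeric",
    rrInterval = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  vals <- c(
    object@vencThroughPlane, object@vencInPlane, object@nInterleaves,
    object@spiralReadoutDuration, object@temporalResolution, object@fov,
    object@matrixSize, object@nReconstructedPhases, object@sliceThickness,
    object@navigatorWindow, object@rrInterval
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    return("all acquisition parameters must be finite and strictly positive")
  }
  if (object@matrixSize %% 2 != 0) {
    return("matrixSize must be even")
  }
  TRUE
})

#' Parametric motion model of the myocardial annulus
#'
#' A separable velocity model v(t, theta, d) = f(t) * m(theta) * g(d) per
#' direction: global velocity-time profiles built from periodic Gaussian
#' bump trains (one bump per named peak), a cosine regional amplitude
#' modulation in the angular coordinate theta, and a linear transmural
#' gradient in depth d (0 = endocardium, 1 = epicardium) applied to the
#' radial component.
#'
#' @slot sliceLevel one of "basal", "mid", "apical"
#' @slot bumps data.frame of bump parameters: direction, peak, amplitude
#'   (cm/s, the solved bump coefficient), time (ms), width (sigma, ms)
#' @slot prescribed data.frame of the prescribed (ground-truth) peak
#'   amplitudes and times, with the peak class used for time-to-peak
#'   normalisation
#' @slot markers prescribed cardiac phase markers (end systole, diastasis
#'   onset, atrial-systole onset, ms) and the cycle length
#' @slot regional list with `depth` and `phase` (radians) of the cosine
#'   angular amplitude modulation, per direction
#' @slot transmuralGradient slope of the linear endo-to-epi radial
#'   amplitude scaling (factor 1 + g*(0.5 - d))
#' @slot rrInterval cycle length, ms
#' @exportClass MotionModel
setClass("MotionModel",
  representation(
    sliceLevel = "character",
    bumps = "data.frame",
    prescribed = "data.frame",
    markers = "numeric",
    regional = "list",
    transmuralGradient = "numeric",
    rrInterval = "numeric"
  )
)

setValidity("MotionModel", function(object) {
  if (!object@sliceLevel %in% c("basal", "mid", "apical")) {
    return("sliceLevel must be one of 'basal', 'mid', 'apical'")
  }
  if (object@transmuralGradient < -2 || object@transmuralGradient > 2) {
    return("transmural gradient out of range")
  }
  if (nrow(object@bumps) > 0) {
    tm <- object@bumps$time
    if (any(!is.finite(tm)) || any(tm < 0) || any(tm >= object@rrInterval)) {
      return("bump times must lie in [0, rrInterval)")
    }
    for (dd in unique(object@bumps$direction)) {
      td <- object@bumps$time[object@bumps$direction == dd]
      if (is.unsorted(td, strictly = TRUE)) {
        return("prescribed peak times must be strictly increasing per direction")
      }
    }
  }
  TRUE
})

#' A velocity-encoded image series
#'
#' Magnitude images plus four phase image sets (reference, x-, y- and
#' z-encoded) on a common frame grid, with per-frame trigger times.
#' Phase values are in radians, wrapped to [-pi, pi).
#'
#' @slot magnitude array rows x cols x frames
#' @slot phases array rows x cols x frames x 4, sets ordered
#'   c("ref", "x", "y", "z")
#' @slot frameTimes ms from the R-wave, one per frame
#' @slot params the \linkS4class{AcquisitionParams} used
#' @slot pixelSpacing mm per pixel
#' @exportClass EncodedSeries
setClass("EncodedSeries",
  representation(
    magnitude = "array",
    phases = "array",
    frameTimes = "numeric",
    params = "AcquisitionParams",
    pixelSpacing = "numeric"
  )
)

setValidity("EncodedSeries", function(object) {
  dp <- dim(object@phases)
  if (length(dp) != 4 || dp[4] != 4) {
    return("phases must be a rows x cols x frames x 4 array")
  }
  dm <- dim(object@magnitude)
  if (length(dm) != 3 || any(dm != dp[1:3])) {
    return("magnitude must be rows x cols x frames matching phases")
  }
  if (length(object@frameTimes) != dp[3]) {
    return("frameTimes length must equal the number of frames")
  }
  if (any(object@phases < -pi - 1e-9) || any(object@phases >= pi + 1e-9)) {
    return("phase values must lie in [-pi, pi)")
  }
  if (length(object@frameTimes) > 0 &&
      (object@frameTimes[1] < 0 ||
       max(object@frameTimes) >= object@params@rrInterval)) {
    return("frameTimes must satisfy 0 <= t < rrInterval")
  }
  TRUE
})

#' A per-pixel three-component velocity field series
#'
#' Velocities are in cm/s in image coordinates (x = columns increasing
#' rightwards, y = rows increasing downwards, z = slice normal, positive
#' towards the apex).
#'
#' @slot velocities array rows x cols x frames x 3 (components x, y, z)
#' @slot times frame times, ms from the R-wave
#' @slot rrInterval cycle length, ms
#' @slot pixelSpacing mm per pixel
#' @exportClass VelocityFieldSeries
setClass("VelocityFieldSeries",
  representation(
    velocities = "array",
    times = "numeric",
    rrInterval = "numeric",
    pixelSpacing = "numeric"
  )
)

setValidity("VelocityFieldSeries", function(object) {
  dv <- dim(object@velocities)
  if (length(dv) != 4 || dv[4] != 3) {
    return("velocities must be a rows x cols x frames x 3 array")
  }
  if (length(object@times) != dv[3]) {
    return("times length must equal the number of frames")
  }
  if (is.unsorted(object@times, strictly = TRUE)) {
    return("times must be strictly increasing")
  }
  TRUE
})

#' Left-ventricular slice geometry
#'
#' Per-frame endocardial and epicardial contours (closed polygons, mm, in
#' image coordinates with the origin at the image centre), the per-frame
#' centre of mass of the rasterized myocardial mask, and the anterior LV-RV
#' junction landmark defining the polar reference direction.
#'
#' @slot endo list of per-frame n x 2 matrices (x, y in mm)
#' @slot epi list of per-frame n x 2 matrices
#' @slot centres frames x 2 matrix of mask centres of mass (mm)
#' @slot landmark length-2 anterior LV-RV junction position (mm)
#' @slot mask logical array rows x cols x frames, the rasterized myocardium
#' @slot dims c(rows, cols) of the pixel grid
#' @slot pixelSpacing mm per pixel
#' @slot sliceLevel slice level label
#' @exportClass LVGeometry
setClass("LVGeometry",
  representation(
    endo = "list",
    epi = "list",
    centres = "matrix",
    landmark = "numeric",
    mask = "array",
    dims = "numeric",
    pixelSpacing = "numeric",
    sliceLevel = "character"
  )
)

setValidity("LVGeometry", function(object) {
  nf <- length(object@endo)
  if (length(object@epi) != nf || nrow(object@centres) != nf) {
    return("endo, epi and centres must agree on the number of frames")
  }
  if (length(object@landmark) != 2) {
    return("landmark must be a length-2 (x, y) position")
  }
  TRUE
})

#' Cylindrical velocity decomposition of a field series
#'
#' Per-pixel longitudinal, radial and circumferential velocities in the LV
#' cylindrical system: longitudinal positive towards the apex, radial
#' positive towards the slice centre, circumferential positive clockwise as
#' viewed from the apex. Also carries the per-pixel angular coordinate theta
#' (measured from the anterior LV-RV junction direction, increasing towards
#' the lateral wall) and transmural depth.
#'
#' @slot velocities array rows x cols x frames x 3 (long, rad, circ)
#' @slot theta array rows x cols x frames, radians in [0, 2*pi)
#' @slot depth array rows x cols x frames, transmural depth in [0, 1]
#' @slot mask logical array rows x cols x frames
#' @slot times frame times, ms
#' @slot rrInterval cycle length, ms
#' @exportClass CylindricalVelocitySeries
setClass("CylindricalVelocitySeries",
  representation(
    velocities = "array",
    theta = "array",
    depth = "array",
    mask = "array",
    times = "numeric",
    rrInterval = "numeric"
  )
)

#' Angular segment and transmural layer model
#'
#' Integer label arrays partitioning the myocardial mask into angular
#' segments (AHA 6/4-segment or 24 equal-angle schemes) and transmural
#' layers (endocardial, mid-wall, epicardial thirds).
#'
#' @slot segments integer array rows x cols x frames (NA outside the mask)
#' @slot segmentNames character vector naming the angular segments
#' @slot layers integer array rows x cols x frames (1 endo, 2 mid, 3 epi)
#' @slot scheme "aha" or "equal24"
#' @exportClass SegmentModel
setClass("SegmentModel",
  representation(
    segments = "array",
    segmentNames = "character",
    layers = "array",
    scheme = "character"
  )
)

#' A region-averaged velocity-time curve
#'
#' @slot region region label (e.g. "global", an AHA segment name, a layer)
#' @slot direction "longitudinal", "radial" or "circumferential"
#' @slot times ms from the R-wave, strictly increasing
#' @slot values cm/s
#' @slot rrInterval cycle length, ms
#' @exportClass VelocityTimeCurve
setClass("VelocityTimeCurve",
  representation(
    region = "character",
    direction = "character",
    times = "numeric",
    values = "numeric",
    rrInterval = "numeric"
  )
)

setValidity("VelocityTimeCurve", function(object) {
  if (length(object@times) != length(object@values)) {
    return("times and values must have equal length")
  }
  if (is.unsorted(object@times, strictly = TRUE)) {
    return("times must be strictly increasing")
  }
  if (any(!is.finite(object@values))) {
    return("values must be finite")
  }
  if (!object@direction %in% c("longitudinal", "radial", "circumferential")) {
    return("unknown direction")
  }
  TRUE
})

#' Cardiac phase markers
#'
#' The four time points splitting the cycle into systole, early diastole,
#' diastasis and atrial systole.
#'
#' @slot tEndSystole ms from the R-wave to end systole (first negative
#'   radial peak)
#' @slot tDiastasisOnset ms, onset of the mid-diastolic quiescent period
#' @slot tAtrialOnset ms, onset of atrial systole
#' @slot rrInterval cycle length, ms
#' @slot atrialFlagged TRUE when the atrial onset was imputed because no
#'   atrial-systolic radial peak was found
#' @exportClass CardiacPhaseMarkers
setClass("CardiacPhaseMarkers",
  representation(
    tEndSystole = "numeric",
    tDiastasisOnset = "numeric",
    tAtrialOnset = "numeric",
    rrInterval = "numeric",
    atrialFlagged = "logical"
  )
)

setValidity("CardiacPhaseMarkers", function(object) {
  if (!(0 < object@tEndSystole &&
        object@tEndSystole < object@tDiastasisOnset &&
        object@tDiastasisOnset < object@tAtrialOnset &&
        object@tAtrialOnset < object@rrInterval)) {
    return("markers must satisfy 0 < end systole < diastasis onset < atrial onset < rr")
  }
  TRUE
})

#' A set of named velocity peaks with time-to-peak values
#'
#' One row per named peak (S, D, AS for longitudinal/radial; C1, C2, C3 for
#' circumferential) with amplitude (cm/s), time to peak from the R-wave
#' (ms), time to peak as a percentage of systolic or diastolic length, and
#' the fixed-length ms conversion based on average systolic (350 ms) and
#' diastolic (650 ms) durations. Absent peaks are rows with NA amplitude.
#'
#' @slot peaks data.frame with columns peak, class, present, amplitude,
#'   ttp_ms, ttp_percent, ttp_fixed_ms
#' @slot direction velocity direction
#' @slot sliceLevel slice level
#' @slot markers the \linkS4class{CardiacPhaseMarkers} used
#' @slot eOverA magnitude ratio of early-diastolic to atrial-systolic peak
#'   (NA when undefined)
#' @exportClass PeakSet
setClass("PeakSet",
  representation(
    peaks = "data.frame",
    direction = "character",
    sliceLevel = "character",
    markers = "CardiacPhaseMarkers",
    eOverA = "numeric"
  )
)

#' Spiral k-space trajectory
#'
#' An interleaved Archimedean spiral: interleave j is interleave 0 rotated
#' by 2*pi*j/nInterleaves; samples are uniform in arc length along each
#' interleave.
#'
#' @slot kx,ky numeric vectors of k-space coordinates, cycles/mm, all
#'   interleaves concatenated
#' @slot times sample times within the readout, ms
#' @slot interleave integer interleave index (1-based) per sample
#' @slot nInterleaves number of interleaves
#' @slot kmax maximum spatial frequency, cycles/mm
#' @exportClass SpiralTrajectory
setClass("SpiralTrajectory",
  representation(
    kx = "numeric",
    ky = "numeric",
    times = "numeric",
    interleave = "integer",
    nInterleaves = "numeric",
    kmax = "numeric"
  )
)

setValidity("SpiralTrajectory", function(object) {
  n <- length(object@kx)
  if (length(object@ky) != n || length(object@times) != n ||
      length(object@interleave) != n) {
    return("kx, ky, times, interleave must have equal length")
  }
  if (any(sqrt(object@kx^2 + object@ky^2) > object@kmax * (1 + 1e-9))) {
    return("|k| must not exceed kmax")
  }
  TRUE
})

#' Cardiac phase normalization template
#'
#' Target section lengths for the four-section piecewise normalization
#' (systole, early diastole, diastasis, atrial systole) and the uniform
#' output sampling grid.
#'
#' @slot sectionLengths named numeric: systole, early_diastole, diastasis,
#'   atrial_systole (ms)
#' @slot nPoints number of output samples per cycle
#' @exportClass PhaseTemplate
setClass("PhaseTemplate",
  representation(
    sectionLengths = "numeric",
    nPoints = "numeric"
  )
)

setValidity("PhaseTemplate", function(object) {
  if (length(object@sectionLengths) != 4 || any(object@sectionLengths <= 0)) {
    return("four strictly positive section lengths are required")
  }
  if (object@nPoints < 4) {
    return("nPoints must be at least 4")
  }
  TRUE
})

#' 24-segment by time colour grid
#'
#' @slot values 24 x T matrix, cm/s; rows ordered anterior -> lateral ->
#'   inferior -> septal (increasing theta from the anterior junction)
#' @slot direction velocity direction
#' @slot sliceLevel slice level
#' @slot times template times, ms
#' @slot markerIndices column indices of the three internal section
#'   boundaries (end systole, diastasis onset, atrial-systole onset)
#' @exportClass ColourGrid
setClass("ColourGrid",
  representation(
    values = "matrix",
    direction = "character",
    sliceLevel = "character",
    times = "numeric",
    markerIndices = "integer"
  )
)

setValidity("ColourGrid", function(object) {
  if (nrow(object@values) != 24) {
    return("a colour grid has exactly 24 angular segment rows")
  }
  if (ncol(object@values) != length(object@times)) {
    return("times must match the number of columns")
  }
  if (is.unsorted(object@markerIndices, strictly = TRUE)) {
    return("marker indices must be strictly increasing")
  }
  TRUE
})
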