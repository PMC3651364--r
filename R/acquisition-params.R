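#' Construct acquisition parameters
#'
#' Defaults reproduce the reference spiral phase velocity mapping protocol:
#' velocity sensitivities of 30 cm/s through-plane and 20 cm/s in-plane,
#' 13 spiral interleaves of 12 ms, 21 ms acquired temporal resolution,
#' 360 mm field of view on a 256 x 256 matrix (1.4 mm pixels),
#' retrospective interpolation to 60 cardiac phases, 8 mm slice thickness
#' and a 5 mm navigator acceptance window.
#'
#' @param vencThroughPlane through-plane velocity sensitivity, cm/s
#' @param vencInPlane in-plane velocity sensitivity, cm/s
#' @param nInterleaves number of spiral interleaves
#' @param spiralReadoutDuration spiral readout duration, ms
#' @param temporalResolution acquired frame spacing, ms
#' @param fov field of view, mm
#' @param matrixSize reconstruction matrix size (even)
#' @param nReconstructedPhases number of retrospectively interpolated phases
#' @param sliceThickness slice thickness, mm
#' @param navigatorWindow navigator acceptance window, mm
#' @param rrInterval cardiac cycle length, ms
#' @return an \linkS4class{AcquisitionParams} object
#' @examples
#' p <- AcquisitionParams()
#' pixelSpacing(p)   # 1.40625 mm
#' @export
AcquisitionParams <- function(vencThroughPlane = 30, vencInPlane = 20,
                              nInterleaves = 13, spiralReadoutDuration = 12,
                              temporalResolution = 21, fov = 360,
                              matrixSize = 256, nReconstructedPhases = 60,
                              sliceThickness = 8, navigatorWindow = 5,
                              rrInterval = 1000) {
  new("AcquisitionParams",
    vencThroughPlane = vencThroughPlane, vencInPlane = vencInPlane,
    nInterleaves = nInterleaves, spiralReadoutDuration = spiralReadoutDuration,
    temporalResolution = temporalResolution, fov = fov,
    matrixSize = matrixSize, nReconstructedPhases = nReconstructedPhases,
    sliceThickness = sliceThickness, navigatorWindow = navigatorWindow,
    rrInterval = rrInterval
  )
}

#' @describeIn AcquisitionParams acquired pixel spacing, mm (fov/matrix)
#' @param x an AcquisitionParams object
#' @export
setMethod("pixelSpacing", "AcquisitionParams", function(x) {
  x@fov / x@matrixSize
})

#' @describeIn AcquisitionParams cardiac cycle length, ms
#' @export
setMethod("rrInterval", "AcquisitionParams", function(x) x@rrInterval)

#' Velocity sensitivity accessors
#'
#' @param x an \linkS4class{AcquisitionParams} object
#' @return venc in cm/s
#' @export
vencThroughPlane <- function(x) x@vencThroughPlane

#' @rdname vencThroughPlane
#' @export
vencInPlane <- function(x) x@vencInPlane

#' @rdname vencThroughPlane
#' @export
matrixSize <- function(x) x@matrixSize

#' @rdname vencThroughPlane
#' @export
fieldOfView <- function(x) x@fov

#' @rdname vencThroughPlane
#' @export
nInterleaves <- function(x) x@nInterleaves

#' @rdname vencThroughPlane
#' @export
nReconstructedPhases <- function(x) x@nReconstructedPhases

#' @rdname vencThroughPlane
#' @export
temporalResolution <- function(x) x@temporalResolution

#' Number of cardiac cycles for one complete acquisition
#'
#' One interleave is acquired per cardiac cycle; the reference and the
#' three velocity-encoded datasets are acquired on consecutive cycles
#' after a single dummy cycle, so a full three-directional acquisition
#' takes nInterleaves * 4 + 1 cycles (53 for the default protocol,
#' assuming 100\% respiratory efficiency).
#'
#' @param params an \linkS4class{AcquisitionParams} object
#' @param nDatasets number of datasets per acquisition (reference + 3
#'   encodings)
#' @param nDummy number of dummy cycles
#' @return number of cardiac cycles
#' @export
acquisitionCycles <- function(params, nDatasets = 4, nDummy = 1) {
  params@nInterleaves * nDatasets + nDummy
}

setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams\n")
  cat(sprintf("  venc: %g cm/s through-plane, %g cm/s in-plane\n",
              object@vencThroughPlane, object@vencInPlane))
  cat(sprintf("  %g spiral interleaves of %g ms; temporal resolution %g ms\n",
              object@nInterleaves, object@spiralReadoutDuration,
              object@temporalResolution))
  cat(sprintf("  FOV %g mm, matrix %g (%.5g mm pixels), %g phases, RR %g ms\n",
              object@fov, object@matrixSize, pixelSpacing(object),
              object@nReconstructedPhases, object@rrInterval))
})
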