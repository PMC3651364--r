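#' @rdname frameTimes
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname pixelSpacing
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname rrInterval
#' @export
setGeneric("rrInterval", function(x) standardGeneric("rrInterval"))

#' @rdname sliceLevel
#' @export
setGeneric("sliceLevel", function(x) standardGeneric("sliceLevel"))

#' @rdname velocities
#' @export
setGeneric("velocities", function(x) standardGeneric("velocities"))

#' @rdname peakTable
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))

#' @rdname velocityProfile
#' @export
setGeneric("velocityProfile",
  function(model, direction, times, theta = NULL, depth = NULL)
    standardGeneric("velocityProfile"))

#' @rdname curveTimes
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))

#' @rdname curveValues
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' @rdname segmentNames
#' @export
setGeneric("segmentNames", function(x) standardGeneric("segmentNames"))

#' @rdname gridValues
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
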