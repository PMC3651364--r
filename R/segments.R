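# Angular segment schemes, transmural layers, and region averaging.

.ahaNames6 <- c("anterior", "anterolateral", "inferolateral",
                "inferior", "inferoseptal", "anteroseptal")
.ahaNames4 <- c("anterior", "lateral", "inferior", "septal")

#' Assign angular segments
#'
#' Partitions the myocardial mask into angular segments using half-open
#' bins [a, b) starting at theta = 0 (the anterior LV-RV junction), theta
#' increasing from anterior towards the lateral wall. The "aha" scheme
#' yields the standard six 60-degree segments for basal and mid slices
#' (anterior, anterolateral, inferolateral, inferior, inferoseptal,
#' anteroseptal) and four 90-degree segments for apical slices (anterior,
#' lateral, inferior, septal); "equal24" yields 24 equal 15-degree
#' segments.
#'
#' @param geom an \linkS4class{LVGeometry}
#' @param scheme "aha" or "equal24"
#' @return a \linkS4class{SegmentModel} (with transmural layer labels from
#'   \code{\link{assignLayers}} included)
#' @export
assignSegments <- function(geom, scheme = c("aha", "equal24")) {
  scheme <- match.arg(scheme)
  if (scheme == "aha") {
    if (geom@sliceLevel == "apical") {
      nSeg <- 4L
      segNames <- .ahaNames4
    } else {
      nSeg <- 6L
      segNames <- .ahaNames6
    }
  } else {
    nSeg <- 24L
    segNames <- sprintf("seg%02d", 1:24)
  }
  polar <- .pixelPolar(geom)
  seg <- array(NA_integer_, dim = dim(polar$theta))
  idx <- polar$mask
  seg[idx] <- pmin(floor(polar$theta[idx] / (2 * pi) * nSeg), nSeg - 1) + 1L
  layers <- .layerLabels(polar)
  new("SegmentModel",
    segments = seg, segmentNames = segNames, layers = layers, scheme = scheme
  )
}

# Layer labels from transmural depth: thirds [0,1/3), [1/3,2/3), [2/3,1].
.layerLabels <- function(polar) {
  lay <- array(NA_integer_, dim = dim(polar$depth))
  idx <- polar$mask
  lay[idx] <- pmin(floor(polar$depth[idx] * 3), 2) + 1L
  lay
}

#' Assign transmural layers
#'
#' At each of 360 equally spaced angles around the polar centre, the
#' endocardium-to-epicardium ray is split at depths 1/3 and 2/3; each
#' myocardial pixel is labelled endocardial, mid-wall or epicardial by the
#' depth interval of its nearest ray.
#'
#' @param geom an \linkS4class{LVGeometry}
#' @return integer array rows x cols x frames: 1 = endocardial, 2 =
#'   mid-wall, 3 = epicardial, NA outside the mask
#' @export
assignLayers <- function(geom) {
  .layerLabels(.pixelPolar(geom))
}

#' @describeIn assignSegments segment names of a segment model
#' @param x a SegmentModel
#' @export
setMethod("segmentNames", "SegmentModel", function(x) x@segmentNames)

setMethod("show", "SegmentModel", function(object) {
  cat(sprintf("SegmentModel: scheme '%s', %d angular segments x 3 layers\n",
              object@scheme, length(object@segmentNames)))
})

#' Region-averaged velocity-time curve
#'
#' Unweighted mean over the pixels of a region, per frame, for one
#' direction. Regions are "global" (the whole mask), an angular segment
#' name, a layer name ("endo", "mid-wall", "epi"), or a
#' segment/layer combination given as list(segment =, layer =).
#'
#' @param cyl a \linkS4class{CylindricalVelocitySeries}
#' @param segModel the matching \linkS4class{SegmentModel}
#' @param region region specification (see Details)
#' @param direction "longitudinal", "radial" or "circumferential"
#' @return a \linkS4class{VelocityTimeCurve}
#' @export
regionAverage <- function(cyl, segModel, region = "global",
                          direction = c("longitudinal", "radial",
                                        "circumferential")) {
  direction <- match.arg(direction)
  dirIdx <- match(direction, c("longitudinal", "radial", "circumferential"))
  layerNames <- c("endo", "mid-wall", "epi")

  segWanted <- NULL
  layWanted <- NULL
  label <- "global"
  if (is.list(region)) {
    segWanted <- region$segment
    layWanted <- region$layer
    label <- paste(stats::na.omit(c(segWanted, layWanted)), collapse = "/")
  } else if (region != "global") {
    if (region %in% layerNames) layWanted <- region else segWanted <- region
    label <- region
  }
  segIdx <- if (!is.null(segWanted)) {
    i <- match(segWanted, segModel@segmentNames)
    if (is.na(i)) stop("unknown segment: ", segWanted)
    i
  }
  layIdx <- if (!is.null(layWanted)) {
    i <- match(layWanted, layerNames)
    if (is.na(i)) stop("unknown layer: ", layWanted)
    i
  }

  nf <- dim(cyl@velocities)[3]
  vals <- numeric(nf)
  for (k in seq_len(nf)) {
    sel <- cyl@mask[, , k]
    if (!is.null(segIdx)) {
      sel <- sel & !is.na(segModel@segments[, , k]) &
        segModel@segments[, , k] == segIdx
    }
    if (!is.null(layIdx)) {
      sel <- sel & !is.na(segModel@layers[, , k]) &
        segModel@layers[, , k] == layIdx
    }
    if (!any(sel)) stop("empty region '", label, "' in frame ", k)
    v <- cyl@velocities[, , k, dirIdx]
    vals[k] <- mean(v[sel])
  }
  new("VelocityTimeCurve",
    region = label, direction = direction, times = cyl@times, values = vals,
    rrInterval = cyl@rrInterval
  )
}

#' @describeIn regionAverage curve times, ms
#' @param x a VelocityTimeCurve
#' @export
setMethod("curveTimes", "VelocityTimeCurve", function(x) x@times)

#' @describeIn regionAverage curve values, cm/s
#' @export
setMethod("curveValues", "VelocityTimeCurve", function(x) x@values)

#' @describeIn regionAverage cycle length, ms
#' @export
setMethod("rrInterval", "VelocityTimeCurve", function(x) x@rrInterval)

setMethod("show", "VelocityTimeCurve", function(object) {
  cat(sprintf(
    "VelocityTimeCurve '%s' (%s): %d samples, range %.2f..%.2f cm/s\n",
    object@region, object@direction, length(object@times),
    min(object@values), max(object@values)
  ))
})

#' Construct a velocity-time curve
#'
#' @param times ms from the R-wave, strictly increasing
#' @param values cm/s
#' @param rr cycle length, ms
#' @param region,direction labels
#' @return a \linkS4class{VelocityTimeCurve}
#' @export
velocityTimeCurve <- function(times, values, rr,
                              region = "global", direction = "radial") {
  new("VelocityTimeCurve",
    region = region, direction = direction, times = times, values = values,
    rrInterval = rr
  )
}
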