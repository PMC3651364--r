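# LV slice geometry: mask rasterization, centre of mass, polar reference,
# and the cylindrical velocity decomposition.

#' Compute the LV slice geometry from contours
#'
#' Rasterizes the myocardial mask (pixel-centre point-in-polygon: inside
#' the epicardial contour and outside the endocardial one), computes the
#' per-frame centre of mass of the binary mask, and records the anterior
#' LV-RV junction landmark defining the polar reference direction.
#'
#' Contours are in mm in image coordinates with the origin at the image
#' centre (x along columns rightwards, y along rows downwards).
#'
#' @param endo,epi lists of per-frame closed-contour matrices (n x 2, mm)
#' @param landmark anterior LV-RV junction, c(x, y) in mm
#' @param dims pixel grid size c(rows, cols)
#' @param spacing pixel spacing, mm
#' @param sliceLevel slice level label
#' @return an \linkS4class{LVGeometry}
#' @export
computeGeometry <- function(endo, epi, landmark, dims, spacing,
                            sliceLevel = "mid") {
  nf <- length(endo)
  if (length(epi) != nf) stop("endo and epi must have one contour per frame")
  grid <- pixelGrid(dims, spacing)
  px <- as.vector(grid$x)
  py <- as.vector(grid$y)
  mask <- array(FALSE, dim = c(dims[1], dims[2], nf))
  centres <- matrix(0, nf, 2)
  for (k in seq_len(nf)) {
    inEpi <- pointInPolygon(px, py, epi[[k]])
    inEndo <- pointInPolygon(px, py, endo[[k]])
    if (any(inEndo & !inEpi)) {
      stop("contours are not nested: endocardium must lie inside epicardium")
    }
    m <- inEpi & !inEndo
    if (!any(m)) stop("empty myocardial mask in frame ", k)
    mask[, , k] <- m
    centres[k, ] <- c(mean(px[m]), mean(py[m]))
  }
  new("LVGeometry",
    endo = endo, epi = epi, centres = centres, landmark = landmark,
    mask = mask, dims = as.numeric(dims), pixelSpacing = spacing,
    sliceLevel = sliceLevel
  )
}

#' @describeIn computeGeometry slice level of a geometry
#' @param x an LVGeometry
#' @export
setMethod("sliceLevel", "LVGeometry", function(x) x@sliceLevel)

#' @describeIn computeGeometry pixel spacing of a geometry, mm
#' @export
setMethod("pixelSpacing", "LVGeometry", function(x) x@pixelSpacing)

#' Per-frame mask centres of mass
#'
#' @param geom an \linkS4class{LVGeometry}
#' @return frames x 2 matrix of (x, y) centres, mm
#' @export
maskCentres <- function(geom) geom@centres

setMethod("show", "LVGeometry", function(object) {
  cat(sprintf("LVGeometry (%s slice): %d frames, %g x %g grid at %.3g mm\n",
              object@sliceLevel, length(object@endo), object@dims[1],
              object@dims[2], object@pixelSpacing))
  cat(sprintf("  landmark (%.1f, %.1f) mm; %d myocardial pixels in frame 1\n",
              object@landmark[1], object@landmark[2], sum(object@mask[, , 1])))
})

# Per-pixel polar coordinates of a geometry: angular coordinate theta from
# the polar reference direction, transmural depth by nearest-ray lookup
# among 360 equally spaced endo->epi rays, and the mask with
# centre-coincident pixels excluded.
.pixelPolar <- function(geom) {
  nf <- length(geom@endo)
  grid <- pixelGrid(geom@dims, geom@pixelSpacing)
  theta <- array(0, dim = c(geom@dims[1], geom@dims[2], nf))
  depth <- array(NA_real_, dim = c(geom@dims[1], geom@dims[2], nf))
  mask <- geom@mask
  angles <- seq(0, 2 * pi, length.out = 361)[-361]
  for (k in seq_len(nf)) {
    ctr <- geom@centres[k, ]
    dx <- grid$x - ctr[1]
    dy <- grid$y - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    mask[, , k] <- mask[, , k] & (r >= 1e-9)
    ref <- geom@landmark - ctr
    th <- matrix(angleFromReference(as.vector(dx), as.vector(dy), ref),
                 geom@dims[1], geom@dims[2])
    theta[, , k] <- th
    rEndo <- polygonRadiusAt(geom@endo[[k]], ctr, ref, angles)
    rEpi <- polygonRadiusAt(geom@epi[[k]], ctr, ref, angles)
    if (any(rEpi - rEndo <= 0)) {
      stop("zero or negative wall thickness on a ray in frame ", k)
    }
    rayIdx <- (round(th / (2 * pi) * 360) %% 360) + 1
    dep <- (r - rEndo[rayIdx]) / (rEpi[rayIdx] - rEndo[rayIdx])
    dep <- pmin(pmax(dep, 0), 1)
    dep[!mask[, , k]] <- NA_real_
    depth[, , k] <- dep
  }
  list(theta = theta, depth = depth, mask = mask)
}

#' Decompose velocities into the LV cylindrical system
#'
#' Transforms image-coordinate velocities into longitudinal, radial and
#' circumferential components per pixel: longitudinal = v_z (motion
#' towards the apex positive), radial = -(v . r_hat) with r_hat pointing
#' outward from the per-frame mask centre (motion towards the slice centre
#' positive), circumferential = v . c_hat with c_hat the
#' clockwise-viewed-from-apex tangent. The per-pixel angular coordinate
#' theta is measured from the polar reference direction (centre to the
#' anterior LV-RV junction), increasing from anterior towards the lateral
#' wall; transmural depth is assigned by the 360-ray construction of
#' \code{\link{assignLayers}}.
#'
#' @param field a \linkS4class{VelocityFieldSeries}
#' @param geom the matching \linkS4class{LVGeometry}
#' @return a \linkS4class{CylindricalVelocitySeries}
#' @export
toCylindrical <- function(field, geom) {
  d <- dim(field@velocities)
  nf <- d[3]
  if (length(geom@endo) != nf) {
    stop("geometry frames do not match the velocity series")
  }
  polar <- .pixelPolar(geom)
  grid <- pixelGrid(geom@dims, geom@pixelSpacing)
  vel <- array(0, dim = c(d[1], d[2], nf, 3))
  mask <- polar$mask
  for (k in seq_len(nf)) {
    ctr <- geom@centres[k, ]
    dx <- grid$x - ctr[1]
    dy <- grid$y - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    r[r < 1e-9] <- 1
    rhx <- dx / r; rhy <- dy / r
    chx <- -rhy; chy <- rhx
    vx <- field@velocities[, , k, 1]
    vy <- field@velocities[, , k, 2]
    vel[, , k, 1] <- field@velocities[, , k, 3]
    vel[, , k, 2] <- -(vx * rhx + vy * rhy)
    vel[, , k, 3] <- vx * chx + vy * chy
  }
  theta <- polar$theta
  depth <- polar$depth
  new("CylindricalVelocitySeries",
    velocities = vel, theta = theta, depth = depth, mask = mask,
    times = field@times, rrInterval = field@rrInterval
  )
}

#' @describeIn toCylindrical velocity array (long, rad, circ)
#' @param x a CylindricalVelocitySeries
#' @export
setMethod("velocities", "CylindricalVelocitySeries", function(x) x@velocities)

#' @describeIn toCylindrical frame times, ms
#' @export
setMethod("frameTimes", "CylindricalVelocitySeries", function(x) x@times)

setMethod("show", "CylindricalVelocitySeries", function(object) {
  d <- dim(object@velocities)
  cat(sprintf(
    "CylindricalVelocitySeries: %d x %d pixels, %d frames (long, rad, circ)\n",
    d[1], d[2], d[3]
  ))
})
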