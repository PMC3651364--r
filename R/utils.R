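# Internal numerical helpers shared across modules.

# Wrap phase values into [-pi, pi).
wrapPhase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  # guard: x %% y can return y for tiny negative x
  out[out >= pi] <- -pi
  out
}

# Round half away from zero to `digits` decimals, as printed tables do.
# The 1e-9 guard absorbs binary representation noise in values that are
# exactly representable in decimal (e.g. products of table entries).
roundHalfAway <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Trapezoidal integral and cumulative integral over a time grid.
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

# Centered 2-D discrete Fourier transforms: the (N/2+1, N/2+1) element of
# the input is treated as the origin in both domains.
fftshift2 <- function(m) {
  d <- dim(m)
  m[c((d[1] / 2 + 1):d[1], 1:(d[1] / 2)), c((d[2] / 2 + 1):d[2], 1:(d[2] / 2))]
}

ifftshift2 <- function(m) {
  d <- dim(m)
  m[c((d[1] / 2 + 1):d[1], 1:(d[1] / 2)), c((d[2] / 2 + 1):d[2], 1:(d[2] / 2))]
}

ft2c <- function(m) fftshift2(stats::fft(ifftshift2(m)))

ift2c <- function(m) {
  fftshift2(stats::fft(ifftshift2(m), inverse = TRUE)) / length(m)
}

# Vectorized even-odd point-in-polygon (pixel-centre membership).
# px, py: query points; poly: n x 2 closed or open polygon.
pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1
  }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Angle of points (px, py) measured from reference direction `ref`
# (unit 2-vector, image coordinates with y down), increasing in the
# clockwise-viewed-from-apex sense; result in [0, 2*pi).
angleFromReference <- function(px, py, ref) {
  ref <- ref / sqrt(sum(ref^2))
  perp <- c(-ref[2], ref[1])
  th <- atan2(px * perp[1] + py * perp[2], px * ref[1] + py * ref[2])
  th %% (2 * pi)
}

# Linear interpolation on a closed cycle: values at `times` within a cycle
# of length rr are interpolated at `query` times, wrapping across the
# R-wave boundary.
cyclicInterp <- function(times, values, query, rr) {
  n <- length(times)
  tExt <- c(times[n] - rr, times, times[1] + rr)
  vExt <- c(values[n], values, values[1])
  stats::approx(tExt, vExt, xout = query %% rr, rule = 2)$y
}

# Polygon radius as a function of angle about a centre, interpolated at
# requested angles (radians from `ref`). Assumes a star-shaped contour.
polygonRadiusAt <- function(poly, centre, ref, angles) {
  dx <- poly[, 1] - centre[1]
  dy <- poly[, 2] - centre[2]
  th <- angleFromReference(dx, dy, ref)
  r <- sqrt(dx^2 + dy^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  thExt <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  rExt <- c(r[length(r)], r, r[1])
  stats::approx(thExt, rExt, xout = angles %% (2 * pi), rule = 2)$y
}

# Pixel-centre coordinate grids in mm, origin at the image centre.
# Returns list(x, y) of rows x cols matrices (x along columns, y along rows,
# y increasing downwards).
pixelGrid <- function(dims, spacing) {
  rows <- dims[1]; cols <- dims[2]
  xs <- (seq_len(cols) - (cols / 2 + 0.5)) * spacing
  ys <- (seq_len(rows) - (rows / 2 + 0.5)) * spacing
  list(
    x = matrix(rep(xs, each = rows), rows, cols),
    y = matrix(rep(ys, times = cols), rows, cols)
  )
}
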