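# Interleaved Archimedean spiral trajectory and the exact (direct DFT)
# k-space sampling operator used as the forward oracle for gridding.

#' Design an interleaved spiral trajectory
#'
#' An idealized constant-angular-density Archimedean spiral with samples
#' uniform in arc length (constant gradient magnitude). Interleave j is
#' interleave 0 rotated by 2*pi*j/nInterleaves. The number of turns per
#' interleave, matrix/(2*nInterleaves), makes the radial spacing of the
#' full interleave set exactly 1/fov, i.e. fully sampled at the stated
#' field of view; k_max = matrix/(2*fov).
#'
#' @param params an \linkS4class{AcquisitionParams}
#' @param samplesPerInterleave ADC samples per interleave readout
#' @return a \linkS4class{SpiralTrajectory}
#' @examples
#' tr <- designTrajectory(AcquisitionParams())
#' tr@kmax  # 256/(2*360) cycles/mm
#' @export
designTrajectory <- function(params = AcquisitionParams(),
                             samplesPerInterleave = 1024) {
  kmax <- params@matrixSize / (2 * params@fov)
  nInt <- params@nInterleaves
  nTurns <- params@matrixSize / (2 * nInt)

  # arc-length reparameterisation of k(tau) = kmax * tau * e^{i*2*pi*nTurns*tau}
  tauDense <- seq(0, 1, length.out = 50 * samplesPerInterleave)
  ang <- 2 * pi * nTurns * tauDense
  kxD <- kmax * tauDense * cos(ang)
  kyD <- kmax * tauDense * sin(ang)
  seg <- sqrt(diff(kxD)^2 + diff(kyD)^2)
  s <- c(0, cumsum(seg))
  sTarget <- seq(0, s[length(s)], length.out = samplesPerInterleave)
  tau <- stats::approx(s, tauDense, xout = sTarget)$y
  ang <- 2 * pi * nTurns * tau
  kx0 <- kmax * tau * cos(ang)
  ky0 <- kmax * tau * sin(ang)
  t0 <- seq(0, params@spiralReadoutDuration,
            length.out = samplesPerInterleave)

  kx <- numeric(0); ky <- numeric(0); tt <- numeric(0); il <- integer(0)
  for (j in seq_len(nInt)) {
    rot <- 2 * pi * (j - 1) / nInt
    kx <- c(kx, kx0 * cos(rot) - ky0 * sin(rot))
    ky <- c(ky, kx0 * sin(rot) + ky0 * cos(rot))
    tt <- c(tt, t0)
    il <- c(il, rep(j, samplesPerInterleave))
  }
  new("SpiralTrajectory",
    kx = kx, ky = ky, times = tt, interleave = as.integer(il),
    nInterleaves = nInt, kmax = kmax
  )
}

setMethod("show", "SpiralTrajectory", function(object) {
  cat(sprintf(
    "SpiralTrajectory: %g interleaves, %d samples each, kmax %.4f cycles/mm\n",
    object@nInterleaves, sum(object@interleave == 1L), object@kmax
  ))
})

# Pixel-centre coordinates for the Fourier modules: x_i = (i - 1 - M/2) * d,
# so index M/2 + 1 is the origin (matching the centered FFT helpers).
.fourierGridCoords <- function(m, spacing) {
  (seq_len(m) - 1 - m / 2) * spacing
}

#' Sample k-space of an image along a trajectory (direct DFT)
#'
#' The exact discrete Fourier sum S(k) = sum_p x_p exp(-2*pi*i k . r_p)
#' over pixel centres r_p, evaluated at every trajectory coordinate. This
#' is the forward oracle: exact but O(pixels x samples).
#'
#' @param image a square numeric (or complex) matrix
#' @param trajectory a \linkS4class{SpiralTrajectory}
#' @param fov field of view of the image, mm
#' @return complex vector of k-space samples aligned with the trajectory
#' @export
sampleKspace <- function(image, trajectory, fov) {
  m <- nrow(image)
  if (ncol(image) != m) stop("image must be square")
  spacing <- fov / m
  coords <- .fourierGridCoords(m, spacing)
  X <- matrix(rep(coords, each = m), m, m)   # x along columns
  Y <- matrix(rep(coords, times = m), m, m)  # y along rows
  xv <- as.vector(X); yv <- as.vector(Y); img <- as.vector(image)
  n <- length(trajectory@kx)
  out <- complex(n)
  chunk <- max(1, floor(2^21 / (m * m) * 16))
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    ph <- outer(trajectory@kx[idx], xv) + outer(trajectory@ky[idx], yv)
    out[idx] <- as.vector(exp(-2i * pi * ph) %*% img)
  }
  out
}

#' Adjoint of the k-space sampling operator
#'
#' x_p = sum_j y_j exp(+2*pi*i k_j . r_p); the exact conjugate-transpose of
#' \code{\link{sampleKspace}}, used for adjoint consistency testing.
#'
#' @param kdata complex k-space samples
#' @param trajectory a \linkS4class{SpiralTrajectory}
#' @param matrixSize output image size
#' @param fov field of view, mm
#' @return complex matrixSize x matrixSize image
#' @export
adjointSampleKspace <- function(kdata, trajectory, matrixSize, fov) {
  m <- matrixSize
  spacing <- fov / m
  coords <- .fourierGridCoords(m, spacing)
  X <- matrix(rep(coords, each = m), m, m)
  Y <- matrix(rep(coords, times = m), m, m)
  xv <- as.vector(X); yv <- as.vector(Y)
  n <- length(kdata)
  acc <- complex(m * m)
  chunk <- max(1, floor(2^21 / (m * m) * 16))
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    ph <- outer(xv, trajectory@kx[idx]) + outer(yv, trajectory@ky[idx])
    acc <- acc + as.vector(exp(2i * pi * ph) %*% kdata[idx])
  }
  matrix(acc, m, m)
}
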