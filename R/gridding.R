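# Convolution gridding reconstruction (Kaiser-Bessel kernel, 2x
# oversampling, analytic radial density compensation) and zero-filled
# Fourier interpolation.

# Kaiser-Bessel kernel of full width W grid cells, evaluated at offset u.
.kbKernel <- function(u, W, beta) {
  z <- 1 - (2 * u / W)^2
  out <- numeric(length(u))
  ok <- z > 0
  out[ok] <- besselI(beta * sqrt(z[ok]), 0) / besselI(beta, 0)
  out
}

# Continuous Fourier transform of the KB kernel at image position n/N
# (relative shape only; the overall scale is removed by PSF calibration).
.kbDeapodize <- function(n, N, W, beta) {
  x <- n / N
  arg <- beta^2 - (pi * W * x)^2
  out <- numeric(length(x))
  pos <- arg > 0
  out[pos] <- sinh(sqrt(arg[pos])) / sqrt(arg[pos])
  out[!pos] <- sin(sqrt(-arg[!pos])) / sqrt(-arg[!pos])
  out[abs(arg) < 1e-12] <- 1
  out / (sinh(beta) / beta)
}

# Radially binned inverse-density compensation: weight = annulus area /
# sample count on rings of width 1/(4*fov), areas clipped at kmax, with a
# cap against near-empty outer bins. Matches the true density of a
# uniform-arc-length spiral (nearly uniform, with a dense centre where
# the interleaves converge) without Voronoi tessellation.
.radialDensityWeights <- function(traj, fov) {
  kr <- sqrt(traj@kx^2 + traj@ky^2)
  db <- 1 / (4 * fov)
  bins <- floor(kr / db)
  cnt <- table(bins)
  bi <- as.integer(names(cnt))
  outerR <- pmin((bi + 1) * db, traj@kmax)
  innerR <- pmin(bi * db, traj@kmax)
  area <- pi * (outerR^2 - innerR^2)
  wmap <- area / as.numeric(cnt)
  wmap <- pmin(wmap, 2 * stats::median(wmap))
  wmap[match(bins, bi)]
}

# Core gridding: density-compensated KB spreading onto the oversampled
# grid, centered inverse FFT, deapodization, central crop.
.gridOnce <- function(kdata, traj, matrixSize, fov, os, W, beta) {
  N <- os * matrixSize
  dk <- 1 / (os * fov)
  cIdx <- N / 2 + 1

  w <- .radialDensityWeights(traj, fov)
  val <- kdata * w

  px <- traj@kx / dk + cIdx
  py <- traj@ky / dk + cIdx
  bx <- floor(px); by <- floor(py)

  idxAll <- integer(0)
  valAll <- complex(0)
  for (ox in -1:2) {
    ix <- bx + ox
    kxw <- .kbKernel(ix - px, W, beta)
    for (oy in -1:2) {
      iy <- by + oy
      kyw <- .kbKernel(iy - py, W, beta)
      wk <- kxw * kyw
      keep <- wk > 0 & ix >= 1 & ix <= N & iy >= 1 & iy <= N
      if (!any(keep)) next
      idxAll <- c(idxAll, (ix[keep] - 1L) * N + iy[keep])  # row = y, col = x
      valAll <- c(valAll, val[keep] * wk[keep])
    }
  }
  G <- matrix(0 + 0i, N, N)
  if (length(idxAll) > 0) {
    re <- rowsum(Re(valAll), idxAll)
    im <- rowsum(Im(valAll), idxAll)
    G[as.integer(rownames(re))] <- complex(real = re, imaginary = im)
  }

  img <- ift2c(G)
  dea <- .kbDeapodize(seq_len(N) - cIdx, N, W, beta)
  img <- img / outer(dea, dea)
  lo <- (N - matrixSize) / 2
  img[lo + seq_len(matrixSize), lo + seq_len(matrixSize)]
}

#' Gridding reconstruction of non-Cartesian k-space data
#'
#' Standard convolution gridding: samples are density-compensated with a
#' radially binned inverse-density weight derived from the trajectory
#' (uniform-arc-length spirals are nearly uniform in k-space density,
#' with a denser centre where the interleaves converge), spread onto a 2x
#' oversampled Cartesian grid with a Kaiser-Bessel kernel (width 4 grid
#' cells, beta per the standard oversampling formula), inverse Fourier
#' transformed, deapodized by the kernel transform, and cropped to the
#' target matrix. The overall scale is calibrated on the point-spread
#' function (gridding of unit k-space data), so a delta at the image
#' centre reconstructs with unit amplitude.
#'
#' @param kdata complex k-space samples
#' @param trajectory the matching \linkS4class{SpiralTrajectory}
#' @param matrixSize output matrix size
#' @param fov field of view, mm
#' @param oversampling grid oversampling factor
#' @param kernelWidth Kaiser-Bessel kernel full width, oversampled grid cells
#' @return complex matrixSize x matrixSize reconstructed image
#' @export
gridReconstruct <- function(kdata, trajectory, matrixSize, fov,
                            oversampling = 2, kernelWidth = 4) {
  if (length(kdata) == 0) stop("kdata is empty")
  if (length(kdata) != length(trajectory@kx)) {
    stop("kdata length must match the trajectory")
  }
  os <- oversampling
  W <- kernelWidth
  beta <- pi * sqrt((W / os)^2 * (os - 0.5)^2 - 0.8)
  img <- .gridOnce(kdata, trajectory, matrixSize, fov, os, W, beta)
  psf <- .gridOnce(rep(1 + 0i, length(kdata)), trajectory, matrixSize, fov,
                   os, W, beta)
  # point-source reference: a unit delta reconstructed from the circular
  # k-space support peaks at (points inside the |k| <= kmax disc) / M^2,
  # not at 1
  u <- (seq_len(matrixSize) - 1 - matrixSize / 2) / fov
  nIn <- sum(sqrt(outer(u^2, u^2, "+")) <= trajectory@kmax + 1e-12)
  blPeak <- nIn / matrixSize^2
  img * blPeak / Re(psf[matrixSize / 2 + 1, matrixSize / 2 + 1])
}

#' Zero-filled Fourier interpolation
#'
#' Transforms the image to k-space, symmetrically zero-pads to
#' factor x size (splitting the Nyquist row/column to keep a real result),
#' and inverse transforms. The output pixel pitch is the input pitch
#' divided by the factor; original sample values are reproduced exactly at
#' the original grid positions.
#'
#' @param image square numeric matrix with even size
#' @param factor integer interpolation factor >= 1
#' @return (factor*size) x (factor*size) numeric matrix
#' @export
zeroFillInterpolate <- function(image, factor = 2) {
  if (factor != round(factor) || factor < 1) {
    stop("factor must be a positive integer")
  }
  m <- nrow(image)
  if (ncol(image) != m || m %% 2 != 0) stop("image must be square, even size")
  if (factor == 1) return(image)
  K <- ft2c(image)
  N <- factor * m
  o <- (N - m) / 2
  Kp <- matrix(0 + 0i, N, N)
  Kp[o + seq_len(m), o + seq_len(m)] <- K
  # split the Nyquist row and column between -m/2 and +m/2 for realness
  r1 <- o + 1; r2 <- o + m + 1
  Kp[r2, ] <- 0.5 * Kp[r1, ]
  Kp[r1, ] <- 0.5 * Kp[r1, ]
  Kp[, r2] <- 0.5 * Kp[, r1]
  Kp[, r1] <- 0.5 * Kp[, r1]
  Re(ift2c(Kp)) * factor^2
}
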