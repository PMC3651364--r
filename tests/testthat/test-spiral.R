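test_that("the designed trajectory has the stated geometry", {
  tr <- designTrajectory(AcquisitionParams(), samplesPerInterleave = 256)
  expect_equal(tr@kmax, 256 / (2 * 360))
  expect_equal(tr@nInterleaves, 13)
  expect_equal(length(unique(tr@interleave)), 13)
  kr <- sqrt(tr@kx^2 + tr@ky^2)
  expect_lte(max(kr), tr@kmax * (1 + 1e-9))
  # each interleave starts at k = 0
  starts <- which(!duplicated(tr@interleave))
  expect_equal(max(kr[starts]), 0)
  # rotating interleave 1 by 2*pi/13 reproduces interleave 2
  i1 <- tr@interleave == 1L
  i2 <- tr@interleave == 2L
  a <- 2 * pi / 13
  rx <- tr@kx[i1] * cos(a) - tr@ky[i1] * sin(a)
  ry <- tr@kx[i1] * sin(a) + tr@ky[i1] * cos(a)
  expect_equal(rx, tr@kx[i2], tolerance = 1e-12)
  expect_equal(ry, tr@ky[i2], tolerance = 1e-12)
})

test_that("direct k-space sampling matches the Fourier oracle", {
  m <- 16
  fov <- m * 1.5
  set.seed(21)
  img <- matrix(rnorm(m * m), m, m)
  # Cartesian query points expressed as a trajectory-like object
  u <- (seq_len(m) - 1 - m / 2) / fov
  kx <- rep(u, each = m)
  ky <- rep(u, times = m)
  tr <- new("SpiralTrajectory", kx = kx, ky = ky,
            times = numeric(length(kx)),
            interleave = rep(1L, length(kx)), nInterleaves = 1,
            kmax = max(sqrt(kx^2 + ky^2)) + 1e-9)
  s <- sampleKspace(img, tr, fov)
  # centered FFT oracle: ref[ky index, kx index]; column-major vectorisation
  # has ky fast within each kx column, matching the query ordering
  ref <- spiralPVM:::ft2c(img)
  refv <- as.vector(ref)
  expect_lt(max(abs(s - refv)) / max(abs(refv)), 1e-10)
  # DC sample of a constant image is value x pixel count
  trDC <- new("SpiralTrajectory", kx = 0, ky = 0, times = 0,
              interleave = 1L, nInterleaves = 1, kmax = 1)
  expect_equal(Re(sampleKspace(matrix(2, m, m), trDC, fov)), 2 * m * m)
})

test_that("shifting the image applies the expected linear phase", {
  m <- 16
  fov <- m * 1.5
  set.seed(31)
  img <- matrix(0, m, m)
  img[5:11, 5:11] <- rnorm(49)  # zero border so a 1-pixel shift is linear
  tr <- designTrajectory(AcquisitionParams(fov = fov, matrixSize = m),
                         samplesPerInterleave = 64)
  s0 <- sampleKspace(img, tr, fov)
  shifted <- img[, c(m, seq_len(m - 1))]  # shift +1 pixel in x (columns)
  s1 <- sampleKspace(shifted, tr, fov)
  expect_lt(max(abs(s1 - s0 * exp(-2i * pi * tr@kx * fov / m))) /
              max(abs(s0)), 1e-10)
})

test_that("sampling and its adjoint satisfy the inner-product identity", {
  m <- 16
  fov <- 24
  tr <- designTrajectory(AcquisitionParams(fov = fov, matrixSize = m),
                         samplesPerInterleave = 128)
  set.seed(41)
  x <- matrix(complex(real = rnorm(m * m), imaginary = rnorm(m * m)), m, m)
  y <- complex(real = rnorm(length(tr@kx)), imaginary = rnorm(length(tr@kx)))
  lhs <- sum(sampleKspace(x, tr, fov) * Conj(y))
  rhs <- sum(x * Conj(adjointSampleKspace(y, tr, m, fov)))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-8)
})

test_that("gridding reconstructs a disc phantom and is linear", {
  m <- 32
  fov <- 45
  p <- AcquisitionParams(fov = fov, matrixSize = m)
  coords <- (seq_len(m) - 1 - m / 2) * fov / m
  R <- sqrt(outer(coords^2, coords^2, "+"))
  disc <- matrix(as.numeric(R <= fov / 4), m, m)
  tr <- designTrajectory(p, samplesPerInterleave = 640)
  kd <- sampleKspace(disc, tr, fov)
  rec <- Re(gridReconstruct(kd, tr, m, fov))
  # reference: the disc as representable from the sampled k-space support
  # (a sharp edge cannot beat circular band-limitation)
  K <- spiralPVM:::ft2c(disc)
  u <- (seq_len(m) - 1 - m / 2) / fov
  K[sqrt(outer(u^2, u^2, "+")) > tr@kmax] <- 0
  bl <- Re(spiralPVM:::ift2c(K))
  nrmse <- sqrt(mean((rec - bl)^2)) / sqrt(mean(bl^2))
  expect_lt(nrmse, 0.05)
  # all-zero data give an all-zero image; doubling doubles
  expect_equal(max(abs(gridReconstruct(kd * 0, tr, m, fov))), 0)
  rec2 <- gridReconstruct(2 * kd, tr, m, fov)
  expect_lt(max(abs(rec2 - 2 * gridReconstruct(kd, tr, m, fov))) /
              max(abs(rec2)), 1e-10)
  expect_error(gridReconstruct(complex(0), tr, m, fov), "empty")
})

test_that("reconstruction error grows as interleaves are removed", {
  m <- 32
  fov <- 45
  coords <- (seq_len(m) - 1 - m / 2) * fov / m
  R <- sqrt(outer(coords^2, coords^2, "+"))
  disc <- matrix(as.numeric(R <= fov / 4), m, m)
  K <- spiralPVM:::ft2c(disc)
  u <- (seq_len(m) - 1 - m / 2) / fov
  K[sqrt(outer(u^2, u^2, "+")) > m / (2 * fov)] <- 0
  bl <- Re(spiralPVM:::ift2c(K))
  nrmse <- vapply(c(13, 6, 3), function(ni) {
    p <- AcquisitionParams(fov = fov, matrixSize = m, nInterleaves = ni)
    tr <- designTrajectory(p, samplesPerInterleave = 640)
    kd <- sampleKspace(disc, tr, fov)
    rec <- Re(gridReconstruct(kd, tr, m, fov))
    sqrt(mean((rec - bl)^2)) / sqrt(mean(bl^2))
  }, numeric(1))
  expect_lt(nrmse[1], nrmse[2])
  expect_lt(nrmse[2], nrmse[3])
})

test_that("zero-filling interpolates without altering original samples", {
  m <- 16
  # band-limited image: inverse transform of a compact random spectrum
  set.seed(51)
  K <- matrix(0 + 0i, m, m)
  K[m / 2 + (-2:2), m / 2 + (-2:2)] <-
    complex(real = rnorm(25), imaginary = rnorm(25))
  K <- K + Conj(K[c(1, m:2), c(1, m:2)])  # hermitian -> real image
  img <- Re(spiralPVM:::ift2c(K))
  out <- zeroFillInterpolate(img, 2)
  expect_equal(dim(out), c(2 * m, 2 * m))
  # original grid positions are the odd samples of the fine grid
  expect_lt(max(abs(out[seq(1, 2 * m, by = 2), seq(1, 2 * m, by = 2)] - img)),
            1e-9)
  # constants stay constant; factor 1 is the identity
  expect_equal(zeroFillInterpolate(matrix(3, m, m), 2),
               matrix(3, 2 * m, 2 * m), tolerance = 1e-12)
  expect_identical(zeroFillInterpolate(img, 1), img)
  expect_error(zeroFillInterpolate(img, 1.5), "integer")
  # the default protocol halves the pitch: 1.40625 mm -> 0.703125 mm
  expect_equal(pixelSpacing(AcquisitionParams()) / 2, 0.703125)
})
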