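test_that("mask centre of mass is symmetric and translation-equivariant", {
  g0 <- annulusGeometry()
  expect_lt(max(abs(maskCentres(g0)[1, ])), 0.1)
  shift <- c(3.5, -2.8)
  g1 <- annulusGeometry(centre = shift)
  expect_equal(maskCentres(g1)[1, ], maskCentres(g0)[1, ] + shift,
               tolerance = 0.05)
})

test_that("centre of mass equals the brute-force pixel average", {
  # irregular (elliptical, offset) contours
  phis <- seq(0, 2 * pi, length.out = 73)[-73]
  endo <- cbind(14 * sin(phis) + 2, -10 * cos(phis) - 1)
  epi <- cbind(24 * sin(phis) + 2, -19 * cos(phis) - 1)
  g <- computeGeometry(list(endo), list(epi), landmark = c(2, -25),
                       dims = c(64, 64), spacing = 1.40625)
  grid <- spiralPVM:::pixelGrid(c(64, 64), 1.40625)
  inEpi <- spiralPVM:::pointInPolygon(as.vector(grid$x), as.vector(grid$y),
                                      epi)
  inEndo <- spiralPVM:::pointInPolygon(as.vector(grid$x), as.vector(grid$y),
                                       endo)
  msk <- inEpi & !inEndo
  expect_equal(maskCentres(g)[1, ],
               c(mean(as.vector(grid$x)[msk]), mean(as.vector(grid$y)[msk])),
               tolerance = 1e-9)
})

test_that("non-nested contours are rejected", {
  expect_error(
    computeGeometry(circleContourList(20), circleContourList(18),
                    landmark = c(0, -25), dims = c(64, 64),
                    spacing = 1.40625),
    "nested"
  )
})

test_that("cylindrical decomposition honours the sign conventions", {
  g <- annulusGeometry()
  n <- 64
  v <- array(0, dim = c(n, n, 1, 3))
  # pixel near the top of the wall, velocity pointing exactly at the
  # centre with speed 2 -> radial +2, circumferential 0
  row <- 15; col <- 33
  grid <- spiralPVM:::pixelGrid(c(n, n), 1.40625)
  r <- sqrt(grid$x[row, col]^2 + grid$y[row, col]^2)
  v[row, col, 1, 1] <- -2 * grid$x[row, col] / r
  v[row, col, 1, 2] <- -2 * grid$y[row, col] / r
  f <- new("VelocityFieldSeries", velocities = v, times = 0,
           rrInterval = 1000, pixelSpacing = 1.40625)
  cyl <- toCylindrical(f, g)
  expect_lt(grid$y[row, col], -20)  # sanity: near the anterior junction
  expect_equal(cyl@velocities[row, col, 1, 2], 2, tolerance = 1e-9)
  expect_equal(cyl@velocities[row, col, 1, 3], 0, tolerance = 1e-9)
  expect_equal(cyl@theta[row, col, 1], 0, tolerance = 0.05)
})

test_that("in-plane speed is preserved by the decomposition", {
  g <- annulusGeometry()
  n <- 64
  set.seed(3)
  v <- array(rnorm(n * n * 3), dim = c(n, n, 1, 3))
  f <- new("VelocityFieldSeries", velocities = v, times = 0,
           rrInterval = 1000, pixelSpacing = 1.40625)
  cyl <- toCylindrical(f, g)
  msk <- cyl@mask[, , 1]
  lhs <- cyl@velocities[, , 1, 2]^2 + cyl@velocities[, , 1, 3]^2
  rhs <- v[, , 1, 1]^2 + v[, , 1, 2]^2
  expect_lt(max(abs(lhs[msk] - rhs[msk])), 1e-12)
  expect_equal(cyl@velocities[, , 1, 1][msk], v[, , 1, 3][msk])
})

test_that("the decomposition is equivariant under quarter rotations", {
  # rotating both the field and the geometry by 90/180/270 degrees maps
  # the (long, rad, circ) maps onto the rotated pixel grid
  n <- 32
  spacing <- 1.40625
  rot90cw <- function(m) t(m[rev(seq_len(nrow(m))), ])  # screen rotation
  set.seed(9)
  for (case in 1:34) {
    for (quarter in 1:3) {
      vx <- matrix(rnorm(n * n), n, n)
      vy <- matrix(rnorm(n * n), n, n)
      endoR <- runif(1, 7, 9); epiR <- runif(1, 12, 15)
      g <- annulusGeometry(endoR, epiR, dims = c(n, n), spacing = spacing)
      v <- array(0, dim = c(n, n, 1, 3))
      v[, , 1, 1] <- vx; v[, , 1, 2] <- vy
      f <- new("VelocityFieldSeries", velocities = v, times = 0,
               rrInterval = 1000, pixelSpacing = spacing)
      cyl <- toCylindrical(f, g)
      # rotate the vectors and the pixel grid by `quarter` quarter turns
      rx <- vx; ry <- vy
      for (q in seq_len(quarter)) {
        tmp <- rot90cw(rx); ry2 <- rot90cw(ry)
        rx <- -ry2; ry <- tmp  # (x, y) -> (-y, x) under screen rotation
      }
      v2 <- array(0, dim = c(n, n, 1, 3))
      v2[, , 1, 1] <- rx; v2[, , 1, 2] <- ry
      f2 <- new("VelocityFieldSeries", velocities = v2, times = 0,
                rrInterval = 1000, pixelSpacing = spacing)
      # geometry is rotation-symmetric except the landmark; rotate it too
      ang <- quarter * pi / 2
      lm <- c((epiR + 2) * sin(ang), -(epiR + 2) * cos(ang))
      g2 <- computeGeometry(circleContourList(endoR), circleContourList(epiR),
                            landmark = lm, dims = c(n, n), spacing = spacing)
      cyl2 <- toCylindrical(f2, g2)
      radRot <- cyl@velocities[, , 1, 2]
      circRot <- cyl@velocities[, , 1, 3]
      for (q in seq_len(quarter)) {
        radRot <- rot90cw(radRot); circRot <- rot90cw(circRot)
      }
      msk <- cyl2@mask[, , 1]
      expect_lt(max(abs(cyl2@velocities[, , 1, 2][msk] - radRot[msk])), 1e-9)
      expect_lt(max(abs(cyl2@velocities[, , 1, 3][msk] - circRot[msk])), 1e-9)
    }
  }
})

test_that("segment schemes partition the wall as specified", {
  gB <- annulusGeometry(sliceLevel = "basal")
  gA <- annulusGeometry(sliceLevel = "apical")
  sB <- assignSegments(gB, "aha")
  sA <- assignSegments(gA, "aha")
  expect_length(segmentNames(sB), 6)
  expect_identical(segmentNames(sB)[1:2], c("anterior", "anterolateral"))
  expect_length(segmentNames(sA), 4)
  s24 <- assignSegments(gB, "equal24")
  expect_length(segmentNames(s24), 24)
  counts <- table(s24@segments[, , 1])
  expect_length(counts, 24)
  expect_lt(max(counts) / mean(counts), 1.10)
  expect_gt(min(counts) / mean(counts), 0.90)
  # a pixel at theta ~ 0 (straight above the centre) is anterior
  expect_equal(sB@segments[12, 33, 1], 1L)
  expect_error(assignSegments(gB, "wedges"), "arg")
  # segments cover the mask exactly (disjoint labels, union = mask)
  expect_identical(!is.na(sB@segments[, , 1]), gB@mask[, , 1])
})

test_that("transmural layers are thirds of the wall", {
  g <- annulusGeometry(20, 30)
  lay <- assignLayers(g)
  grid <- spiralPVM:::pixelGrid(c(64, 64), 1.40625)
  r <- sqrt(grid$x^2 + grid$y^2)
  msk <- g@mask[, , 1]
  # boundaries at 23.33 and 26.67 mm (with half-pixel tolerance)
  expect_true(all(lay[, , 1][msk & r < 23.33 - 0.8] == 1L, na.rm = TRUE))
  expect_true(all(lay[, , 1][msk & r > 23.34 + 0.8 & r < 26.66 - 0.8] == 2L,
                  na.rm = TRUE))
  expect_true(all(lay[, , 1][msk & r > 26.67 + 0.8] == 3L, na.rm = TRUE))
  # partition: every mask pixel gets exactly one layer
  expect_identical(!is.na(lay[, , 1]), msk)
  # each layer holds roughly a third of the wall
  counts <- table(lay[, , 1])
  expect_true(all(abs(counts / sum(counts) - 1 / 3) < 1 / 3 * 0.2))
  # zero wall thickness is rejected
  expect_error(
    computeGeometry(circleContourList(20), circleContourList(20.0001),
                    landmark = c(0, -25), dims = c(64, 64),
                    spacing = 1.40625),
    "mask|thickness"
  )
})

test_that("region averages are consistent and scale-equivariant", {
  g <- annulusGeometry()
  n <- 64
  set.seed(13)
  v <- array(rnorm(n * n * 2 * 3), dim = c(n, n, 2, 3))
  f <- new("VelocityFieldSeries", velocities = v, times = c(0, 21),
           rrInterval = 1000, pixelSpacing = 1.40625)
  g2 <- annulusGeometry(nf = 2)
  cyl <- toCylindrical(f, g2)
  seg <- assignSegments(g2, "aha")
  # uniform field -> constant curve
  fu <- constantField(c(1, 1, 1), n = n, nframes = 2)
  cylU <- toCylindrical(fu, g2)
  cuU <- regionAverage(cylU, seg, "global", "longitudinal")
  expect_equal(curveValues(cuU), c(1, 1))
  # global curve equals the pixel-count-weighted mean of AHA segment curves
  glob <- regionAverage(cyl, seg, "global", "radial")
  segCurves <- lapply(segmentNames(seg), function(s) {
    regionAverage(cyl, seg, s, "radial")
  })
  wts <- vapply(1:6, function(i) sum(seg@segments[, , 1] == i, na.rm = TRUE),
                numeric(1))
  recon <- Reduce(`+`, Map(function(cu, w) curveValues(cu) * w,
                           segCurves, wts)) / sum(wts)
  expect_equal(curveValues(glob), recon, tolerance = 1e-9)
  # scaling the field scales the curve
  f2 <- f; f2@velocities <- 3 * f2@velocities
  cyl3 <- toCylindrical(f2, g2)
  expect_equal(curveValues(regionAverage(cyl3, seg, "global", "radial")),
               3 * curveValues(glob), tolerance = 1e-12)
  expect_error(regionAverage(cyl, seg, "apex"), "unknown")
})
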