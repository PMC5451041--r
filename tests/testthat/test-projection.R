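geomSmall <- projectionGeometry(nAngles = 42L, imageSize = 64L,
                                spacing = 2.6)

test_that("forward projection: zero image, chord length, linearity", {
  z <- matrix(0, 64, 64)
  expect_true(all(sinogramValues(forwardProject(z, geomSmall)) == 0))

  # uniform disc: central bin equals diameter x activity
  disc <- discImage(64, 2.6, radius = 40, value = 2)
  sino <- sinogramValues(forwardProject(disc, geomSmall))
  for (a in c(1, 15, 30)) {
    got <- sino[a, 32]
    expect_lt(abs(got - 2 * 80), 2 * 2.6 * 2)  # within one bin width
  }
  # linearity
  s2 <- sinogramValues(forwardProject(2 * disc, geomSmall))
  expect_equal(s2, 2 * sino, tolerance = 1e-12)
})

test_that("projector pair satisfies the adjoint identity", {
  set.seed(5)
  x <- matrix(runif(64 * 64), 64, 64)
  y <- matrix(runif(42 * 64), 42, 64)
  Ax <- sinogramValues(forwardProject(x, geomSmall))
  Aty <- backProject(y, geomSmall)
  lhs <- sum(Ax * y)
  rhs <- sum(x * Aty)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("attenuation factors: unity for vacuum, closed form for a disc", {
  z <- asMuMap(matrix(0, 64, 64), 2.6)
  af <- attenuationFactors(z, geomSmall)
  expect_true(all(sinogramValues(af) == 1))

  # 20 cm disc, mu = 0.1/cm: central LOR factor exp(-2)
  n <- 256L
  geom <- projectionGeometry(nAngles = 24L, imageSize = n, spacing = 2.6)
  mu <- asMuMap(discImage(n, 2.6, radius = 100, value = 0.1), 2.6)
  f <- sinogramValues(attenuationFactors(mu, geom))
  expect_lt(abs(f[1, 128] - exp(-2)) / exp(-2), 0.01)

  # exponential additivity for disjoint supports
  m1 <- matrix(0, 64, 64); m1[20:25, 20:25] <- 0.05
  m2 <- matrix(0, 64, 64); m2[40:45, 40:45] <- 0.08
  f1 <- sinogramValues(attenuationFactors(asMuMap(m1, 2.6), geomSmall))
  f2 <- sinogramValues(attenuationFactors(asMuMap(m2, 2.6), geomSmall))
  f12 <- sinogramValues(attenuationFactors(asMuMap(m1 + m2, 2.6), geomSmall))
  expect_equal(f12, f1 * f2, tolerance = 1e-10)

  tmp <- asMuMap(matrix(0, 64, 64), 2.6)
  tmp@lac[1] <- -0.1
  expect_error(attenuationFactors(tmp, geomSmall), "negative")
})

test_that("emission simulation is seeded, calibrated and noise-free exact", {
  act <- discImage(64, 2.6, radius = 40, value = 500)
  mu <- asMuMap(discImage(64, 2.6, radius = 40, value = 0.05), 2.6)
  s1 <- simulateEmission(act, mu, geomSmall, totalCounts = 1e5, rngSeed = 4L)
  s2 <- simulateEmission(act, mu, geomSmall, totalCounts = 1e5, rngSeed = 4L)
  expect_identical(sinogramValues(s1), sinogramValues(s2))
  s3 <- simulateEmission(act, mu, geomSmall, totalCounts = 1e5, rngSeed = 5L)
  expect_false(identical(sinogramValues(s1), sinogramValues(s3)))

  # noise-free expectation: rescaled attenuated forward projection
  s0 <- simulateEmission(act, mu, geomSmall, totalCounts = 1e5,
                         poisson = FALSE)
  fp <- sinogramValues(forwardProject(act, geomSmall)) *
    sinogramValues(attenuationFactors(mu, geomSmall))
  expect_equal(sinogramValues(s0), fp * s0@countScale, tolerance = 1e-10)
  expect_equal(sum(sinogramValues(s0)), 1e5, tolerance = 1e-8)

  # vacuum: counts proportional to the plain projection
  s4 <- simulateEmission(act, asMuMap(matrix(0, 64, 64), 2.6), geomSmall,
                         totalCounts = 1e5, poisson = FALSE)
  plain <- sinogramValues(forwardProject(act, geomSmall))
  expect_equal(sinogramValues(s4), plain * s4@countScale, tolerance = 1e-10)

  expect_error(simulateEmission(matrix(0, 64, 64), mu, geomSmall,
                                totalCounts = 100), "configuration error")
})

test_that("Poisson means converge to the noise-free expectation", {
  geomTiny <- projectionGeometry(nAngles = 6L, imageSize = 32L,
                                 spacing = 2.6)
  act <- discImage(32, 2.6, radius = 20, value = 100)
  mu <- asMuMap(discImage(32, 2.6, radius = 20, value = 0.05), 2.6)
  lam <- sinogramValues(simulateEmission(act, mu, geomTiny, 1e4,
                                         poisson = FALSE))
  acc <- matrix(0, nrow(lam), ncol(lam))
  for (k in 1:400) {
    acc <- acc + sinogramValues(
      simulateEmission(act, mu, geomTiny, 1e4, rngSeed = 1000L + k))
  }
  m <- acc / 400
  se <- sqrt(lam / 400)
  sel <- lam > 1
  expect_true(all(abs(m[sel] - lam[sel]) < 4 * se[sel] + 1e-9))
})

test_that("OSEM: fixed points, scale equivariance, parameter recovery", {
  act <- discImage(64, 2.6, radius = 50, value = 1000)
  mu <- asMuMap(discImage(64, 2.6, radius = 50, value = 0.096), 2.6)
  counts <- simulateEmission(act, mu, geomSmall, totalCounts = 1e6,
                             poisson = FALSE)
  af <- attenuationFactors(mu, geomSmall)

  # all-zero counts collapse to the zero image
  zeroCounts <- new("Sinogram", values = matrix(0, 42, 64),
                    geometry = geomSmall, countScale = 1)
  img0 <- osemReconstruct(zeroCounts, af, reconConfig(iterations = 3L,
                                                      subsets = 21L))
  expect_true(all(img0 == 0))

  # matched AC recovers the disc (<5% interior bias, 10 iters, no filter)
  rc <- reconConfig(iterations = 10L, subsets = 21L, postFilterFWHM = 0)
  img <- osemReconstruct(counts, af, rc)
  est <- img / counts@countScale
  interior <- discImage(64, 2.6, radius = 35) == 1
  expect_lt(abs(mean(est[interior]) - 1000) / 1000, 0.05)
  expect_true(all(img >= 0))

  # doubling the counts doubles the image (noise-free)
  counts2 <- new("Sinogram", values = 2 * sinogramValues(counts),
                 geometry = geomSmall, countScale = counts@countScale)
  img2 <- osemReconstruct(counts2, af, rc)
  expect_equal(img2, 2 * img, tolerance = 1e-6)

  # count conservation at convergence: reprojection matches data < 1%
  reproj <- sinogramValues(af) *
    sinogramValues(forwardProject(img, geomSmall))
  expect_lt(abs(sum(reproj) - sum(sinogramValues(counts))) /
              sum(sinogramValues(counts)), 0.01)

  expect_error(osemReconstruct(counts, af,
                               reconConfig(subsets = 5L)),
               "configuration error")
})

test_that("OSEM with one subset reproduces MLEM update-for-update", {
  act <- discImage(64, 2.6, radius = 40, value = 100)
  mu <- asMuMap(discImage(64, 2.6, radius = 40, value = 0.03), 2.6)
  counts <- simulateEmission(act, mu, geomSmall, totalCounts = 1e5,
                             rngSeed = 9L)
  af <- attenuationFactors(mu, geomSmall)

  # independent MLEM oracle built from the exported projector pair
  y <- sinogramValues(counts)
  a <- sinogramValues(af)
  x <- matrix(1, 64, 64)
  sens <- backProject(a, geomSmall)
  for (it in 1:3) {
    yhat <- a * sinogramValues(forwardProject(x, geomSmall))
    ratio <- y / pmax(yhat, 1e-12)
    ratio[y == 0 & yhat <= 1e-12] <- 0
    upd <- backProject(a * ratio, geomSmall) / pmax(sens, 1e-12)
    upd[sens <= 1e-12] <- 0
    x <- x * upd
  }
  img <- osemReconstruct(counts, af,
                         reconConfig(iterations = 3L, subsets = 1L,
                                     postFilterFWHM = 0))
  expect_equal(img, x, tolerance = 1e-10)
})

test_that("AC bias direction follows the attenuation-map error", {
  # AC map lower than truth inside a sub-region biases that region low
  n <- 96L
  geom <- projectionGeometry(nAngles = 48L, imageSize = n, spacing = 2.6)
  act <- discImage(n, 2.6, radius = 110, value = 100)
  muT <- discImage(n, 2.6, radius = 110, value = 0.096)
  sub <- discImage(n, 2.6, radius = 25, center = c(35, 35)) > 0.5
  muLow <- muT; muLow[sub] <- 0.04
  counts <- simulateEmission(act, asMuMap(muT, 2.6), geom, 1e6,
                             poisson = FALSE)
  rc <- reconConfig(iterations = 6L, subsets = 12L, postFilterFWHM = 0)
  imgT <- osemReconstruct(counts, attenuationFactors(asMuMap(muT, 2.6),
                                                     geom), rc)
  imgL <- osemReconstruct(counts, attenuationFactors(asMuMap(muLow, 2.6),
                                                     geom), rc)
  expect_lt(mean(imgL[sub]), 0.8 * mean(imgT[sub]))
  # and a uniformly raised AC map biases high
  muHi <- muT * 1.3
  imgH <- osemReconstruct(counts, attenuationFactors(asMuMap(muHi, 2.6),
                                                     geom), rc)
  expect_gt(mean(imgH[sub]), mean(imgT[sub]))
})

test_that("SUV scaling matches its definition elementwise", {
  set.seed(77)
  img <- matrix(runif(64, 0, 5000), 8, 8)
  dose <- 3.5e8; weight <- 7e4; cal <- 12.5
  suv <- suvVolume(suvScale(img, dose, weight, cal))
  oracle <- array(0, c(8, 8, 1))
  for (i in 1:8) for (j in 1:8)
    oracle[i, j, 1] <- (img[i, j] / cal) / (dose / weight)
  expect_equal(suv, oracle, tolerance = 1e-12)
  # concentration equal to dose/weight gives SUV 1
  one <- suvScale(matrix(dose / weight, 4, 4), dose, weight, 1)
  expect_true(all(abs(suvVolume(one) - 1) < 1e-12))
  expect_true(all(suvVolume(suvScale(matrix(0, 4, 4), dose, weight)) == 0))
  expect_error(suvScale(img, -1, weight), "dose")
})
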