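test_that("zero-phase pupil is a real non-negative top-hat over the aperture", {
  cfg <- smallConfig()
  p <- makePupil(cfg, cfg@lambdaEm)
  expect_true(all(Im(p@values) == 0))
  expect_true(all(Re(p@values) >= 0))
  expect_true(all(Re(p@values) %in% c(0, 1)))
  # support confined to |k| <= NA/lambda
  kg <- outer(pidiff:::kAxis(64, 0.05)^2, pidiff:::kAxis(64, 0.05)^2, `+`)
  kmax2 <- (cfg@numericalAperture / (cfg@lambdaEm * 1e-3))^2
  expect_true(all(Mod(p@values)[kg > kmax2] == 0))
})

test_that("doubling NA roughly quadruples the pupil support area", {
  cfg1 <- smallConfig(na = 0.45, n = 256, dx = 0.02)
  cfg2 <- smallConfig(na = 0.90, n = 256, dx = 0.02)
  n1 <- sum(Mod(makePupil(cfg1, 500)@values) > 0)
  n2 <- sum(Mod(makePupil(cfg2, 500)@values) > 0)
  expect_gt(n2 / n1, 3.5)
  expect_lt(n2 / n1, 4.5)
})

test_that("a constant aberration phase leaves the PSF unchanged", {
  cfg <- smallConfig(n = 32)
  phase <- matrix(1.234, 32, 32)
  h0 <- widefieldPSF(cfg)
  h1 <- widefieldPSF(cfg, aberrationPhase = phase)
  expect_lt(max(abs(psfValues(h1) - psfValues(h0))), 1e-12)
})

test_that("invalid apertures and unresolvable pupils are rejected", {
  expect_error(opticalConfig(1.4, 480, 520, refractiveIndex = 1.33,
                             gridShape = c(1, 32, 32)),
               "refractiveIndex")
  cfg <- smallConfig(na = 0.45, n = 16, dx = 0.02) # aperture < 1 sample
  expect_error(makePupil(cfg, 520), "sampling error")
})

test_that("FFT autocorrelation matches the brute-force double loop", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- if (seed == 1) 8 else 16
    Q <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
    pup <- new("PupilField", values = Q, kSpacing = c(0.1, 0.1),
               wavelength = 500)
    C <- otfFromPupil(pup)@values
    qa <- pidiff:::ifftshift2(Q)
    Cb <- matrix(0 + 0i, n, n)
    for (k1 in 0:(n - 1)) for (k2 in 0:(n - 1)) {
      s <- 0 + 0i
      for (m1 in 0:(n - 1)) for (m2 in 0:(n - 1))
        s <- s + qa[(m1 + k1) %% n + 1, (m2 + k2) %% n + 1] *
                 Conj(qa[m1 + 1, m2 + 1])
      Cb[k1 + 1, k2 + 1] <- s
    }
    Cb <- pidiff:::fftshift2(Cb)
    expect_lt(max(Mod(C - Cb)) / max(Mod(Cb)), 1e-10)
  }
})

test_that("OTF of a single-sample pupil is flat; |C| peaks at DC", {
  n <- 16
  Q <- matrix(0 + 0i, n, n); Q[9, 9] <- 1 + 0i   # centre sample
  pup <- new("PupilField", values = Q, kSpacing = c(0.1, 0.1),
             wavelength = 500)
  C <- otfFromPupil(pup)@values
  # autocorrelation of a point: non-zero only at K = 0
  expect_equal(Mod(C[9, 9]), 1)
  C[9, 9] <- 0
  expect_lt(max(Mod(C)), 1e-12)
  # Hermitian symmetry and DC maximum for a real disk pupil
  p2 <- makePupil(smallConfig(), 520)
  C2 <- otfFromPupil(p2)@values
  expect_true(Mod(C2[33, 33]) >= max(Mod(C2)) - 1e-9)
  flip <- function(m) m[c(1, nrow(m):2), c(1, ncol(m):2)]
  C2u <- pidiff:::ifftshift2(C2)
  expect_lt(max(Mod(C2u - Conj(flip(C2u)))), 1e-9 * max(Mod(C2)))
})

test_that("amplitudePSF: delta for flat OTF, Parseval, real for Hermitian C", {
  n <- 16
  otf <- new("OTF", values = matrix(1 + 0i, n, n), kSpacing = c(0.1, 0.1))
  u <- amplitudePSF(otf)
  expect_equal(Re(u[9, 9]), 1)
  u[9, 9] <- 0
  expect_lt(max(Mod(u)), 1e-12)
  # Parseval under the chosen normalisation: sum |u|^2 = sum |C|^2 / N
  set.seed(7)
  Cr <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  otf2 <- new("OTF", values = Cr, kSpacing = c(0.1, 0.1))
  u2 <- amplitudePSF(otf2)
  expect_equal(sum(Mod(u2)^2), sum(Mod(Cr)^2) / (n * n), tolerance = 1e-10)
  # OTF from a real pupil is Hermitian -> u real to round-off
  C3 <- otfFromPupil(makePupil(smallConfig(), 500))
  u3 <- amplitudePSF(C3)
  expect_lt(max(abs(Im(u3))), 1e-10 * max(Mod(u3)))
})

test_that("widefield PSF is unit-sum, non-negative and laterally symmetric", {
  cfg <- smallConfig(lamEx = 480, lamEm = 520)
  h <- widefieldPSF(cfg)
  v <- psfValues(h)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_true(all(v >= 0))
  # h(x, y, z) = h(-x, -y, z): reflect about the centre pixel
  sl <- v[1, , ]
  refl <- sl[c(1, 64:2), c(1, 64:2)]
  expect_lt(max(abs(sl - refl)), 1e-9 * max(sl))
})

test_that("focal-plane profile matches the analytic Airy intensity", {
  cfg <- smallConfig(na = 0.9, lamEx = 500, lamEm = 500, n = 512,
                     dx = 16.7 / 512)
  h <- widefieldPSF(cfg)
  sl <- psfKernel(h)
  cy <- 257
  prof <- sl[cy, cy:(cy + 40)] / sl[cy, cy]
  r <- (0:40) * cfg@pixelSizeXY
  v <- 2 * pi * 0.9 * r / 0.5
  airy <- ifelse(v == 0, 1, (2 * besselJ(v, 1) / v)^4)
  expect_lt(max(abs(prof - airy)), 5e-3)
  # first dark ring at 0.61 lambda / NA
  r0 <- firstZeroRadius(h)
  expect_lt(abs(r0 - 0.61 * 0.5 / 0.9) / (0.61 * 0.5 / 0.9), 0.03)
})

test_that("pinhole mask covers the limits: all-pass, degenerate, disk area", {
  cfgBig <- smallConfig(pinhole = 1e4, n = 32)
  expect_true(all(pinholeMask(cfgBig) == 1))
  cfgTiny <- smallConfig(pinhole = 0.01, n = 32)    # < half a pixel
  expect_warning(Tm <- pinholeMask(cfgTiny), "single-pixel")
  expect_equal(sum(Tm), 1)
  expect_equal(Tm[17, 17], 1)
  # rasterised area converges to pi R^2 as the grid refines
  R <- 0.45
  areaErr <- sapply(c(0.05, 0.0125), function(dx) {
    cfg <- smallConfig(pinhole = R, n = round(2.4 / dx), dx = dx)
    abs(sum(pinholeMask(cfg)) * dx^2 - pi * R^2) / (pi * R^2)
  })
  expect_lt(areaErr[2], areaErr[1])
  expect_lt(areaErr[2], 0.02)
})

test_that("confocal PSF: unit-sum, widefield limit, FWHM reduction, monotone", {
  cfgW <- smallConfig(lamEx = 480, lamEm = 520, n = 128, dx = 0.04)
  hw <- widefieldPSF(cfgW)
  # very large pinhole: identical to widefield
  cfgBig <- smallConfig(lamEx = 480, lamEm = 520, n = 128, dx = 0.04,
                        pinhole = 1000)
  hc <- confocalPSF(cfgBig)
  expect_equal(hc@mode, "confocal")
  expect_equal(sum(psfValues(hc)), 1, tolerance = 1e-12)
  expect_true(all(psfValues(hc) >= 0))
  relL2 <- sqrt(sum((psfValues(hc) - psfValues(hw))^2) /
                sum(psfValues(hw)^2))
  expect_lt(relL2, 1e-6)
  # sub-Airy pinhole strictly narrows the lateral FWHM
  AU <- 1.22 * 0.520 / 0.9
  cfgSmall <- smallConfig(lamEx = 480, lamEm = 520, n = 128, dx = 0.04,
                          pinhole = 0.12 * AU)
  hcs <- confocalPSF(cfgSmall)
  expect_lt(lateralFWHM(hcs), lateralFWHM(hw))
  # L2 distance to widefield decreases monotonically with pinhole radius
  prev <- Inf
  for (R in c(0.1, 0.2, 0.4, 0.8, 1.6)) {
    cfgR <- smallConfig(lamEx = 480, lamEm = 520, n = 128, dx = 0.04,
                        pinhole = R)
    d <- sqrt(sum((psfValues(confocalPSF(cfgR)) - psfValues(hw))^2))
    expect_lte(d, prev + 1e-12)
    prev <- d
  }
})

test_that("a 3-D stack carries defocus: energy spreads away from focus", {
  cfg <- opticalConfig(0.9, 500, 520, refractiveIndex = 1.33,
                       pixelSizeXY = 0.05, pixelSizeZ = 0.3,
                       gridShape = c(5, 64, 64))
  h <- widefieldPSF(cfg)
  v <- psfValues(h)
  peaks <- apply(v, 1, max)
  expect_equal(which.max(peaks), 3)      # focal plane on the central slice
  expect_lt(peaks[1], peaks[3])
  expect_lt(peaks[5], peaks[3])
  expect_equal(sum(v), 1, tolerance = 1e-12)
})
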