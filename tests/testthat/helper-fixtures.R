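# Shared fixtures, built in code: small optical configs, delta kernels and
# oracle denoisers used across the suite.

smallConfig <- function(na = 0.9, lamEx = 480, lamEm = 520, n = 64,
                        dx = 0.05, pinhole = Inf, nz = 1) {
  opticalConfig(na, lamEx, lamEm, pinholeRadius = pinhole,
                refractiveIndex = 1.33, pixelSizeXY = dx,
                gridShape = c(nz, n, n))
}

# discrete delta kernel: identity convolution operator
deltaKernel <- function(n) {
  k <- matrix(0, n, n)
  k[n %/% 2 + 1, n %/% 2 + 1] <- 1
  k
}

deltaModel <- function(n, ...) acquisitionModel(deltaKernel(n), ...)

# a smooth, asymmetric but unit-sum test kernel
blurKernel <- function(n, width = 1.5) {
  ax <- xAxisForTest(n)
  k <- exp(-outer(ax^2, ax^2, `+`) / (2 * width^2))
  k / sum(k)
}

xAxisForTest <- function(n) (seq_len(n) - (n %/% 2 + 1))

# brute-force circular 2-D convolution (independent of the FFT route)
bruteConvolve <- function(img, kernel) {
  n <- nrow(img); m <- ncol(img)
  cy <- n %/% 2 + 1; cx <- m %/% 2 + 1
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    acc <- 0
    for (a in 1:n) for (b in 1:m) {
       di <- (i - a + cy - 1) %% n + 1
      dj <- (j - b + cx - 1) %% m + 1
      acc <- acc + img[a, b] * kernel[di, dj]
    }
    out[i, j] <- acc
  }
  out
}

# oracle denoiser that returns the exact noise for a known y0
oracleDenoiser <- function(y0) {
  function(yt, x, gamma) (yt - sqrt(gamma) * y0) / sqrt(1 - gamma)
}

zeroDenoiser <- function(yt, x, gamma) matrix(0, nrow(yt), ncol(yt))

tinyTrainPair <- function(n = 16, seed = 1) {
  set.seed(seed)
  ph <- makePhantom("bars", size = n, n = 2, seed = seed)
  k <- blurKernel(n)
  model <- acquisitionModel(k, photonScale = 1000)
  pr <- acquire(model, ph$image, rngSeed = seed)
  list(pair = list(y0 = 2 * pr@truth - 1, x = 2 * pr@observation - 1,
                   xtilde = 2 * pr@noiseless - 1),
       model = model)
}
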