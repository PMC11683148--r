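test_that("schedules satisfy their defining recursions and limits", {
  s1 <- suppressWarnings(makeSchedule(1, betaRange = c(0.5, 0.5)))
  expect_equal(s1@gamma, 0.5)
  sch <- makeSchedule(1000)
  expect_lt(sch@gamma[1000], 1e-4)
  expect_true(all(diff(sch@gamma) < 0))
  # gamma_t = alpha_t gamma_{t-1} exactly
  expect_equal(sch@gamma, cumprod(1 - sch@beta), tolerance = 0)
  # degenerate all-zero beta warns and gives gamma = 1
  expect_warning(s0 <- makeSchedule(10, betaRange = c(0, 0)), "pure noise")
  expect_true(all(s0@gamma == 1))
  # cosine schedule is valid too
  sc <- makeSchedule(100, kind = "cosine")
  expect_true(all(sc@beta > 0 & sc@beta < 1))
  expect_lt(sc@gamma[100], 0.05)
  expect_error(makeSchedule(10, betaRange = c(0.5, 0.2)), "invalid")
  # sigma choices: beta (upper) and betaTilde (lower)
  st <- makeSchedule(100, betaRange = c(1e-3, 0.2), sigmaChoice = "betaTilde")
  gp <- c(1, st@gamma[-100])
  expect_equal(st@sigma2, (1 - gp) / (1 - st@gamma) * st@beta)
  expect_true(all(st@sigma2 <= st@beta + 1e-12))
})

test_that("qSample hits its limits and closed-form moments", {
  sch <- makeSchedule(100, betaRange = c(1e-3, 0.2))
  set.seed(1)
  y0 <- matrix(runif(64, -1, 1), 8, 8)
  eps <- matrix(rnorm(64), 8, 8)
  expect_error(qSample(sch, y0, 0, eps), "out of range")
  expect_error(qSample(sch, y0, 101, eps), "out of range")
  # gamma ~ 1 at t = 1 of a gentle schedule: nearly y0; pure noise at large t
  schG <- suppressWarnings(makeSchedule(2, betaRange = c(1e-12, 1e-12)))
  expect_equal(qSample(schG, y0, 1, eps), y0, tolerance = 1e-5)
  # Monte-Carlo moments at a mid timestep
  t <- 50
  g <- gammaAt(sch, t)
  draws <- replicate(10000, qSample(sch, y0[1, 1], t, rnorm(1)))
  se <- sqrt(1 - g) / sqrt(10000)
  expect_lt(abs(mean(draws) - sqrt(g) * y0[1, 1]), 3 * se)
  expect_lt(abs(sd(draws) - sqrt(1 - g)), 3 * se)
})

test_that("stepwise chain composition matches the closed form in moments", {
  sch <- makeSchedule(40, betaRange = c(2e-3, 0.25))
  y0 <- 0.7
  tTest <- 25
  set.seed(2)
  n <- 10000
  yt <- rep(y0, n)
  for (t in 1:tTest)
    yt <- sqrt(1 - sch@beta[t]) * yt + sqrt(sch@beta[t]) * rnorm(n)
  g <- gammaAt(sch, tTest)
  se <- sqrt(1 - g) / sqrt(n)
  expect_lt(abs(mean(yt) - sqrt(g) * y0), 3 * se)
  expect_lt(abs(sd(yt) - sqrt(1 - g)), 3 * se)
})

test_that("posterior matches brute-force Bayes on a scalar problem", {
  sch <- makeSchedule(30, betaRange = c(5e-3, 0.3))
  set.seed(3)
  for (i in 1:20) {
    t <- sample(2:30, 1)
    y0 <- runif(1, -1, 1)
    yt <- rnorm(1)
    p <- posteriorParams(sch, matrix(y0, 1, 1), matrix(yt, 1, 1), t)
    # numeric Bayes: posterior over y_{t-1} on a fine grid
    gPrev <- gammaAt(sch, t - 1)
    b <- sch@beta[t]
    grid <- seq(-8, 8, length.out = 40001)
    prior <- dnorm(grid, sqrt(gPrev) * y0, sqrt(1 - gPrev))
    lik <- dnorm(yt, sqrt(1 - b) * grid, sqrt(b))
    w <- prior * lik; w <- w / sum(w)
    mBayes <- sum(w * grid)
    vBayes <- sum(w * (grid - mBayes)^2)
    expect_lt(abs(p$mean[1, 1] - mBayes), 1e-6)
    expect_lt(abs(p$variance - vBayes), 1e-6)
  }
})

test_that("posterior coefficients behave at t = 1 and sum as required", {
  sch <- suppressWarnings(makeSchedule(20, betaRange = c(1e-3, 0.2)))
  y0 <- matrix(0.3, 2, 2); yt <- matrix(-0.5, 2, 2)
  p1 <- posteriorParams(sch, y0, yt, 1)
  expect_equal(p1$mean, y0)          # gamma_0 = 1 forces coefficients (1, 0)
  expect_equal(p1$variance, 0)
  expect_error(posteriorParams(sch, y0, yt, 0), "t = 0")
  for (t in c(2, 7, 20)) {
    g <- gammaAt(sch, t); gp <- gammaAt(sch, t - 1)
    b <- sch@beta[t]; a <- 1 - b
    cSum <- (sqrt(gp) * b + sqrt(a) * (1 - gp)) / (1 - g)
    ones <- matrix(1, 1, 1)
    p <- posteriorParams(sch, ones, ones, t)
    expect_equal(p$mean[1, 1], cSum, tolerance = 1e-12)
  }
})

test_that("muFromEps is consistent with the posterior mean and linear", {
  sch <- makeSchedule(50, betaRange = c(1e-3, 0.2))
  set.seed(4)
  y0 <- matrix(runif(16, -1, 1), 4, 4)
  for (t in c(2, 25, 50)) {
    eps <- matrix(rnorm(16), 4, 4)
    yt <- qSample(sch, y0, t, eps)
    mu <- muFromEps(sch, yt, t, eps)
    post <- posteriorParams(sch, y0, yt, t)
    expect_equal(mu, post$mean, tolerance = 1e-6)
  }
  # beta -> 0 limit returns yt; linearity in epsHat
  schG <- suppressWarnings(makeSchedule(2, betaRange = c(1e-14, 1e-14)))
  yt <- matrix(rnorm(16), 4, 4)
  expect_equal(muFromEps(schG, yt, 1, matrix(1, 4, 4)), yt, tolerance = 1e-6)
  e1 <- matrix(rnorm(16), 4, 4); e2 <- matrix(rnorm(16), 4, 4)
  lhs <- muFromEps(sch, yt, 10, 2 * e1 + 3 * e2)
  rhs <- 2 * muFromEps(sch, yt, 10, e1) + 3 * muFromEps(sch, yt, 10, e2) -
         4 * muFromEps(sch, yt, 10, matrix(0, 4, 4))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("conditioned loss: oracle zero, null denoiser, batch permutation", {
  sch <- makeSchedule(50, betaRange = c(1e-3, 0.2))
  set.seed(5)
  y0 <- matrix(runif(64, -1, 1), 8, 8)
  x <- matrix(runif(64, -1, 1), 8, 8)
  pair <- list(y0 = y0, x = x)
  eps <- matrix(rnorm(64), 8, 8)
  expect_equal(conditionedLoss(sch, oracleDenoiser(y0), pair, 20, eps), 0,
               tolerance = 1e-20)
  expect_equal(conditionedLoss(sch, zeroDenoiser, pair, 20, eps),
               mean(eps^2))
  # mean reduction: average over a batch is order-invariant
  batch <- lapply(1:6, function(i)
    list(pair = pair, t = sample(1:50, 1), eps = matrix(rnorm(64), 8, 8)))
  lossOf <- function(ord) mean(vapply(batch[ord], function(b)
    conditionedLoss(sch, zeroDenoiser, b$pair, b$t, b$eps), numeric(1)))
  expect_identical(lossOf(1:6), lossOf(c(4, 2, 6, 1, 5, 3)))
})

test_that("one-step ancestral sampling inverts the forward draw exactly", {
  # T = 1 with the oracle denoiser returns y0 (no noise added at t = 1)
  sch <- suppressWarnings(makeSchedule(1, betaRange = c(0.7, 0.7)))
  set.seed(6)
  y0 <- matrix(runif(16, -1, 1), 4, 4)
  x <- matrix(0, 4, 4)
  out <- ancestralSample(sch, oracleDenoiser(y0), x, rngSeed = 11)
  expect_equal(out, y0, tolerance = 1e-5)
})

test_that("ancestral sampling is seeded and unbiased for a null denoiser", {
  sch <- suppressWarnings(makeSchedule(20, betaRange = c(5e-3, 0.25)))
  x <- matrix(0, 4, 4)
  o1 <- ancestralSample(sch, zeroDenoiser, x, rngSeed = 3)
  o2 <- ancestralSample(sch, zeroDenoiser, x, rngSeed = 3)
  expect_identical(o1, o2)
  means <- vapply(1:200, function(s)
    mean(ancestralSample(sch, zeroDenoiser, x, rngSeed = s)), numeric(1))
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(200))
})

test_that("exact-posterior sampling reconstructs y0 on a scalar problem", {
  # with the oracle eps-denoiser every transition mean equals the exact
  # posterior mean, so the chain inverts the forward process: MSE is at
  # round-off for any chain length and does not grow with T
  y0 <- matrix(0.6, 1, 1)
  x <- matrix(0, 1, 1)
  ranges <- list(`5` = c(0.1, 0.7), `50` = c(0.01, 0.12))
  mseT <- vapply(c(5, 50), function(Tn) {
    sch <- suppressWarnings(
      makeSchedule(Tn, betaRange = ranges[[as.character(Tn)]]))
    errs <- vapply(1:100, function(s)
      (ancestralSample(sch, oracleDenoiser(y0), x, rngSeed = s) - 0.6)^2,
      numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(mseT[1], 1e-10)
  expect_lte(mseT[2], mseT[1] + 1e-12)
})
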