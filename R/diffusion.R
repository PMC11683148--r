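# DDPM core: variance schedules, the closed-form forward process
# q(y_t | y_0) = N(sqrt(gamma_t) y_0, (1 - gamma_t) I), the exact posterior
# q(y_{t-1} | y_t, y_0), the epsilon-parameterised transition mean, the
# conditioned training loss and ancestral sampling.

#' Build a diffusion variance schedule
#'
#' @param steps number of timesteps T (>= 1).
#' @param kind "linear" (beta linearly spaced over \code{betaRange}) or
#'   "cosine" (squared-cosine signal retention, beta derived and clipped to
#'   0.999).
#' @param betaRange pair (beta_min, beta_max) with 0 <= beta_min <= beta_max
#'   < 1; the defaults are the common convention for T = 1000 and should be
#'   scaled up for shorter chains so that gamma_T stays near 0.
#' @param sigmaChoice "beta" for sigma_t^2 = beta_t (upper bound) or
#'   "betaTilde" for the posterior variance (lower bound).
#' @return A [DiffusionSchedule-class]. A schedule whose gamma_T exceeds 0.05
#'   triggers a warning (the chain does not reach pure noise).
#' @examples
#' sch <- makeSchedule(1000)
#' gammaAt(sch, 1000) < 1e-4
#' @export
makeSchedule <- function(steps, kind = c("linear", "cosine"),
                         betaRange = c(1e-4, 0.02),
                         sigmaChoice = c("beta", "betaTilde")) {
  kind <- match.arg(kind)
  sigmaChoice <- match.arg(sigmaChoice)
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  if (length(betaRange) != 2L || betaRange[1] < 0 || betaRange[2] >= 1 ||
      betaRange[1] > betaRange[2])
    stop("invalid beta range: need 0 <= beta_min <= beta_max < 1")
  if (kind == "linear") {
    beta <- if (steps == 1L) betaRange[2] else
      seq(betaRange[1], betaRange[2], length.out = steps)
  } else {
    s <- 0.008
    f <- function(t) cos((t / steps + s) / (1 + s) * pi / 2)^2
    g <- f(0:steps) / f(0)
    beta <- pmin(1 - g[-1] / g[-(steps + 1)], 0.999)
  }
  alpha <- 1 - beta
  gamma <- cumprod(alpha)
  if (gamma[steps] > 0.05)
    warning(sprintf("gamma_T = %.3g > 0.05: chain does not reach pure noise",
                    gamma[steps]))
  gammaPrev <- c(1, gamma[-steps])
  betaTilde <- (1 - gammaPrev) / (1 - gamma) * beta
  betaTilde[!is.finite(betaTilde)] <- 0          # beta = 0 degenerate steps
  sigma2 <- if (sigmaChoice == "beta") beta else betaTilde
  new("DiffusionSchedule", steps = steps, beta = beta, alpha = alpha,
      gamma = gamma, sigma2 = sigma2, kind = kind, sigmaChoice = sigmaChoice)
}

scheduleAt <- function(schedule, t) {
  t <- as.integer(t)
  if (t < 1L || t > schedule@steps) stop("t out of range 1..T")
  list(beta = schedule@beta[t], alpha = schedule@alpha[t],
       gamma = schedule@gamma[t], gammaPrev = gammaAt(schedule, t - 1L),
       sigma2 = schedule@sigma2[t])
}

#' Sample the forward process at timestep t (closed form)
#'
#' y_t = sqrt(gamma_t) y_0 + sqrt(1 - gamma_t) eps.
#'
#' @param schedule a [DiffusionSchedule-class].
#' @param y0 image (diffusion value convention, [-1, 1]).
#' @param t timestep in 1..T.
#' @param eps standard-normal noise image, same shape as y0.
#' @return noised image y_t.
#' @export
qSample <- function(schedule, y0, t, eps) {
  if (!identical(dim(y0), dim(eps)) && length(y0) != length(eps))
    stop("eps must be shaped like y0")
  p <- scheduleAt(schedule, t)
  sqrt(p$gamma) * y0 + sqrt(1 - p$gamma) * eps
}

#' Exact posterior q(y_{t-1} | y_t, y_0) parameters
#'
#' mean = sqrt(gamma_{t-1}) beta_t / (1 - gamma_t) y_0 +
#'        sqrt(alpha_t) (1 - gamma_{t-1}) / (1 - gamma_t) y_t,
#' variance = beta-tilde_t = (1 - gamma_{t-1}) / (1 - gamma_t) beta_t.
#' At t = 1 (gamma_0 := 1) the mean is y_0 and the variance 0: the chain
#' terminates at the data.
#'
#' @param schedule a [DiffusionSchedule-class].
#' @param y0,yt images.
#' @param t timestep in 1..T.
#' @return list with \code{mean} (image) and \code{variance} (scalar).
#' @export
posteriorParams <- function(schedule, y0, yt, t) {
  if (t < 1) stop("t = 0 has no posterior")
  p <- scheduleAt(schedule, t)
  c0 <- sqrt(p$gammaPrev) * p$beta / (1 - p$gamma)
  ct <- sqrt(p$alpha) * (1 - p$gammaPrev) / (1 - p$gamma)
  list(mean = c0 * y0 + ct * yt,
       variance = (1 - p$gammaPrev) / (1 - p$gamma) * p$beta)
}

#' Transition mean from a noise prediction
#'
#' mu = (1 / sqrt(alpha_t)) (y_t - beta_t / sqrt(1 - gamma_t) eps_hat);
#' with the true eps this equals the exact posterior mean.
#'
#' @param schedule a [DiffusionSchedule-class].
#' @param yt image at timestep t.
#' @param t timestep in 1..T.
#' @param epsHat predicted noise image.
#' @return image: the transition mean.
#' @export
muFromEps <- function(schedule, yt, t, epsHat) {
  p <- scheduleAt(schedule, t)
  (yt - p$beta / sqrt(1 - p$gamma) * epsHat) / sqrt(p$alpha)
}

# A denoiser is either a plain function(yt, x, gamma) -> image (oracles,
# stubs) or a trained network handled by epsPredict().
callDenoiser <- function(denoiser, yt, x, gamma) {
  if (is.function(denoiser)) denoiser(yt, x, gamma)
  else epsPredict(denoiser, yt, x, gamma)
}

#' Conditioned DDPM training loss for one (pair, t, eps) draw
#'
#' || eps - eps_theta(sqrt(gamma_t) y0 + sqrt(1 - gamma_t) eps, x, gamma_t) ||^2
#' with mean reduction over pixels.
#'
#' @param schedule a [DiffusionSchedule-class].
#' @param denoiser function(yt, x, gamma) or trained denoiser object.
#' @param pair an [ImagePair-class]-like list with elements \code{y0} and
#'   \code{x} already in the diffusion value convention ([-1, 1]).
#' @param t timestep in 1..T.
#' @param eps standard-normal noise image.
#' @return scalar loss (mean squared error per pixel).
#' @export
conditionedLoss <- function(schedule, denoiser, pair, t, eps) {
  y0 <- pair$y0; x <- pair$x
  if (!identical(dim(y0), dim(x))) stop("shape mismatch in pair")
  p <- scheduleAt(schedule, t)
  yt <- qSample(schedule, y0, t, eps)
  epsHat <- callDenoiser(denoiser, yt, x, p$gamma)
  mean((eps - epsHat)^2)
}

# Transition mean from a noise prediction, optionally routed through the
# implied clean image clipped to the data range: y0_hat =
# (y_t - sqrt(1 - gamma) eps_hat) / sqrt(gamma), clipped to [-1, 1], then
# the exact posterior mean of (y0_hat, y_t). Without clipping this is
# algebraically identical to muFromEps; the clip is the standard sampler
# safeguard that stops the amplified accumulation of denoiser error along
# the reverse chain.
transitionMean <- function(schedule, yt, t, epsHat, clipDenoised) {
  if (!clipDenoised) return(muFromEps(schedule, yt, t, epsHat))
  p <- scheduleAt(schedule, t)
  y0hat <- (yt - sqrt(1 - p$gamma) * epsHat) / sqrt(p$gamma)
  y0hat <- pmin(pmax(y0hat, -1), 1)
  posteriorParams(schedule, y0hat, yt, t)$mean
}

#' Ancestral sampling of the conditioned reverse chain
#'
#' Starting from y_T ~ N(0, I), iterates
#' y_{t-1} = mu_theta(y_t, t) + sigma_t z_t down to y_0, with no noise added
#' at the final step t = 1. Fully determined by \code{rngSeed}.
#'
#' @param schedule a [DiffusionSchedule-class].
#' @param denoiser function(yt, x, gamma) or trained denoiser object.
#' @param x conditioning image (diffusion value convention).
#' @param rngSeed integer seed.
#' @param trace if TRUE also return the list of intermediate y_t.
#' @param clipDenoised clip the implied clean image to [-1, 1] at every step
#'   before forming the transition mean (default TRUE); with FALSE the mean
#'   is exactly [muFromEps()].
#' @return the sampled y_0 image (or a list with \code{y0} and \code{trace}).
#' @export
ancestralSample <- function(schedule, denoiser, x, rngSeed, trace = FALSE,
                            clipDenoised = TRUE) {
  set.seed(as.integer(rngSeed))
  Tn <- schedule@steps
  yt <- matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
  tr <- if (trace) vector("list", Tn) else NULL
  for (t in seq(Tn, 1L)) {
    p <- scheduleAt(schedule, t)
    epsHat <- callDenoiser(denoiser, yt, x, p$gamma)
    mu <- transitionMean(schedule, yt, t, epsHat, clipDenoised)
    yt <- if (t > 1L)
      mu + sqrt(p$sigma2) * matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
    else mu
    if (trace) tr[[Tn - t + 1L]] <- yt
  }
  if (trace) list(y0 = yt, trace = tr) else yt
}
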