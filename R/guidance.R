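# Physics-informed guidance: the data-likelihood gradient of the linear
# measurement model x = A y + n, n ~ N(xi, xi I), its annealing, optional
# L1/L2 regularisation of the iterate, the guided training loss and the
# guided ancestral sampler. With eta = 0 and no regulariser every routine
# reduces exactly (bitwise, same seeds) to the conditioned DDPM case.

#' Data-fidelity gradient of the measurement log-likelihood
#'
#' Gaussian surrogate measurement model: grad log p(x | y_t) is approximated
#' by A^T (x - xi - A y_t) / xi^2. With \code{xi = 0} the noiseless-target
#' variant is used: the residual is xTilde - A y_t with unit prefactor (the
#' prefactor is irrelevant once the gradient is annealed, which normalises
#' away any constant scale).
#'
#' @param model an [AcquisitionModel-class].
#' @param yt current iterate image.
#' @param xTilde measurement target (noisy observation, or the retained
#'   noiseless measurement when \code{xi = 0}).
#' @param xi Gaussian noise offset; must be > 0 when the target is a noisy
#'   observation.
#' @param noiseless declare the target noiseless; defaults to \code{xi == 0}.
#'   Supplying a noisy target with \code{xi = 0} and \code{noiseless = FALSE}
#'   is a division error.
#' @return image-shaped gradient (the ascent direction of the log-likelihood).
#' @export
dataFidelityGradient <- function(model, yt, xTilde, xi = 0,
                                 noiseless = (xi == 0)) {
  if (!identical(dim(yt), dim(xTilde))) stop("shape mismatch")
  if (noiseless) {
    applyAAdjoint(model, xTilde - applyA(model, yt))
  } else {
    if (xi <= 0) stop("division error: xi must be > 0 for a noisy target")
    applyAAdjoint(model, xTilde - xi - applyA(model, yt)) / xi^2
  }
}

#' Anneal a guidance gradient to norm eta * sqrt(gamma_t)
#'
#' nu_t = eta sqrt(gamma_t) / ||g||_2, so the scaled gradient has L2 norm
#' exactly eta sqrt(gamma_t): guidance weakens as t grows (high noise) and
#' tightens as t -> 0. A zero gradient maps to nu_t = 0.
#'
#' @param gradient image-shaped raw gradient.
#' @param t timestep (bookkeeping only).
#' @param schedule a [DiffusionSchedule-class].
#' @param eta guidance strength.
#' @return list with \code{g} (scaled gradient), \code{nu} and \code{t}.
#' @export
anneal <- function(gradient, t, schedule, eta) {
  gam <- gammaAt(schedule, t)
  nrm <- sqrt(sum(gradient^2))
  nu <- if (nrm > 0) eta * sqrt(gam) / nrm else 0
  list(g = nu * gradient, nu = nu, t = t)
}

#' Gradient of the L1/L2 regulariser lambda_t R(y)
#'
#' lambda_t sign(y) for L1 (subgradient, sign(0) := 0); 2 lambda_t y for L2;
#' zero for "none". The guided sampler subtracts this term from the
#' transition mean so that the shift descends the regulariser.
#'
#' @param yt image.
#' @param kind "none", "l1" or "l2".
#' @param lambdaT regulariser weight at this timestep, >= 0.
#' @return image-shaped gradient.
#' @export
regulariserGradient <- function(yt, kind = c("none", "l1", "l2"), lambdaT) {
  kind <- match.arg(kind)
  switch(kind,
         none = array(0, dim = dim(yt)),
         l1 = lambdaT * sign(yt),
         l2 = 2 * lambdaT * yt)
}

lambdaAt <- function(config, t, steps) {
  lam <- config@lambda
  if (length(lam) == 1L) lam else lam[t]
}

# Shared between the PI loss and the training loop: the noised state, the
# annealed guidance gradient and the regression target eps + sigma_t^2 g.
guidanceTarget <- function(schedule, model, pair, t, eps, config) {
  p <- scheduleAt(schedule, t)
  yt <- qSample(schedule, pair$y0, t, eps)
  if (config@eta > 0) {
    tgt <- if (config@noiselessTarget) {
      if (is.null(pair$xtilde))
        stop("noiseless measurement missing from pair (use_noiseless_target)")
      pair$xtilde
    } else pair$x
    gRaw <- dataFidelityGradient(model, yt, tgt, xi = config@xi,
                                 noiseless = config@noiselessTarget)
    g <- anneal(gRaw, t, schedule, config@eta)$g
    target <- eps + p$sigma2 * g
  } else {
    g <- NULL
    target <- eps
  }
  list(yt = yt, target = target, g = g, gamma = p$gamma)
}

#' Physics-informed training loss for one (pair, t, eps) draw
#'
#' || eps - eps_theta(y_t, x, gamma_t) + sigma_t^2 g ||^2 with C = 1, where
#' g is the annealed data-fidelity gradient evaluated at
#' y_t = sqrt(gamma_t) y0 + sqrt(1 - gamma_t) eps against the retained
#' noiseless measurement (or the noisy observation when
#' \code{noiselessTarget} is off). Mean reduction over pixels. With eta = 0
#' this is exactly the conditioned DDPM loss.
#'
#' @param schedule a [DiffusionSchedule-class].
#' @param denoiser function(yt, x, gamma) or trained denoiser object.
#' @param model an [AcquisitionModel-class].
#' @param pair list with \code{y0}, \code{x} and (for the noiseless variant)
#'   \code{xtilde}, all in the diffusion value convention.
#' @param t timestep in 1..T.
#' @param eps standard-normal noise image.
#' @param config a [GuidanceConfig-class].
#' @return scalar loss.
#' @export
piTrainingLoss <- function(schedule, denoiser, model, pair, t, eps, config) {
  gt <- guidanceTarget(schedule, model, pair, t, eps, config)
  epsHat <- callDenoiser(denoiser, gt$yt, pair$x, gt$gamma)
  mean((gt$target - epsHat)^2)
}

#' Physics-guided ancestral sampling
#'
#' The conditioned ancestral loop with each transition mean shifted by
#' sigma_t^2 (annealed data-fidelity gradient - lambda_t grad R), evaluated
#' at the current iterate against the observation; noise sqrt(sigma_t^2) z
#' added except at t = 1. With eta = 0 and no regulariser the trajectory is
#' bit-identical (same seed) to [ancestralSample()].
#'
#' @param schedule a [DiffusionSchedule-class].
#' @param denoiser function(yt, x, gamma) or trained denoiser object.
#' @param model an [AcquisitionModel-class].
#' @param x observation in the diffusion value convention (also the default
#'   guidance target).
#' @param config a [GuidanceConfig-class].
#' @param rngSeed integer seed.
#' @param target optional explicit guidance target (defaults to x).
#' @param trace if TRUE also return intermediate states.
#' @param clipDenoised clip the implied clean image to [-1, 1] at every step
#'   (default TRUE), as in [ancestralSample()].
#' @return sampled image y_0 (or list with \code{y0} and \code{trace}).
#' @export
piSample <- function(schedule, denoiser, model, x, config, rngSeed,
                     target = NULL, trace = FALSE, clipDenoised = TRUE) {
  if (is.null(target)) target <- x
  set.seed(as.integer(rngSeed))
  Tn <- schedule@steps
  yt <- matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
  tr <- if (trace) vector("list", Tn) else NULL
  for (t in seq(Tn, 1L)) {
    p <- scheduleAt(schedule, t)
    epsHat <- callDenoiser(denoiser, yt, x, p$gamma)
    mu <- transitionMean(schedule, yt, t, epsHat, clipDenoised)
    if (config@eta > 0) {
      gRaw <- dataFidelityGradient(model, yt, target, xi = config@xi,
                                   noiseless = config@xi == 0)
      mu <- mu + p$sigma2 * anneal(gRaw, t, schedule, config@eta)$g
    }
    if (config@regulariser != "none") {
      mu <- mu - p$sigma2 * regulariserGradient(yt, config@regulariser,
                                                lambdaAt(config, t, Tn))
    }
    yt <- if (t > 1L)
      mu + sqrt(p$sigma2) * matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
    else mu
    if (trace) tr[[Tn - t + 1L]] <- yt
  }
  if (trace) list(y0 = yt, trace = tr) else yt
}

#' Repeated guided restorations with mean and uncertainty maps
#'
#' Draws \code{nSamples} guided reconstructions of one observation under
#' different seeds and returns per-pixel mean and standard-deviation maps:
#' the sampler's own estimate of reconstruction uncertainty.
#'
#' @param schedule,denoiser,model,x,config,target as in [piSample()].
#' @param nSamples number of reconstructions.
#' @param rngSeed base seed; sample i uses rngSeed + i - 1.
#' @return list with \code{samples} (list of images), \code{mean}, \code{sd}.
#' @export
restoreEnsemble <- function(schedule, denoiser, model, x, config, nSamples = 8,
                            rngSeed = 1, target = NULL) {
  samples <- lapply(seq_len(nSamples), function(i)
    piSample(schedule, denoiser, model, x, config, rngSeed + i - 1L,
             target = target))
  arr <- simplify2array(samples)
  list(samples = samples,
       mean = apply(arr, c(1, 2), mean),
       sd = apply(arr, c(1, 2), stats::sd))
}
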