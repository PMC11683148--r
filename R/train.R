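# Stochastic training of the conditional denoiser: sample a batch of pairs,
# a timestep t ~ Uniform{1..T} and noise eps ~ N(0, I) per sample, regress
# eps_theta(y_t, x, gamma_t) onto eps + sigma_t^2 g (the physics-informed
# target; g is absent when eta = 0, recovering the conditioned DDPM), and
# take an Adam step on the mean-squared error.

# Adam on the nested parameter list directly (no flattening): the update
# walks the params/grads/moment trees in lockstep.
zeroTree <- function(p) rapply(p, function(x) x * 0, how = "replace")

adamTree <- function(params, grads, m, v, step, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
  rec <- function(p, g, mm, vv) {
    if (is.list(p)) {
      out <- mapply(rec, p, g, mm, vv, SIMPLIFY = FALSE)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m2 <- beta1 * mm + (1 - beta1) * g
      v2 <- beta2 * vv + (1 - beta2) * g * g
      list(p = p - lr * (m2 / c1) / (sqrt(v2 / c2) + eps), m = m2, v = v2)
    }
  }
  out <- rec(params, grads, m, v)
  names(out$p) <- names(params); names(out$m) <- names(params)
  names(out$v) <- names(params)
  out
}

#' Train a conditional (optionally physics-informed) denoiser
#'
#' @param dataset list of training records; each a list with matrices
#'   \code{y0} (ground truth), \code{x} (observation) and \code{xtilde}
#'   (noiseless measurement), all in the diffusion value convention [-1, 1].
#' @param schedule a [DiffusionSchedule-class].
#' @param model an [AcquisitionModel-class], or a list of them indexed by
#'   each pair's \code{psfId} (records from different simulated microscopes
#'   then use their own forward operator in the guidance term); required
#'   when \code{pi = TRUE}.
#' @param config a [GuidanceConfig-class]; \code{eta} is forced to 0 when
#'   \code{pi = FALSE}.
#' @param pi logical: physics-informed loss (TRUE) or plain conditioned DDPM
#'   loss (FALSE).
#' @param spec a [DenoiserSpec-class] (ignored when \code{denoiser} given).
#' @param steps number of optimisation steps.
#' @param batchSize images per step.
#' @param lr Adam learning rate.
#' @param seed integer seed covering weight init, batch order, t and eps.
#' @param denoiser optional [Denoiser-class] to continue training.
#' @param logEvery print the running loss every this many steps (0 = quiet).
#' @return list with \code{denoiser} (trained [Denoiser-class]) and
#'   \code{losses} (per-step training loss trace).
#' @export
trainDenoiser <- function(dataset, schedule, model = NULL,
                          config = guidanceConfig(eta = 0), pi = TRUE,
                          spec = denoiserSpec(), steps = 1000, batchSize = 4,
                          lr = 1e-3, seed = 1, denoiser = NULL,
                          logEvery = 0) {
  if (length(dataset) == 0L) stop("empty dataset")
  if (!pi) config@eta <- 0
  if (config@eta > 0 && is.null(model))
    stop("physics-informed training needs an acquisition model")
  modelFor <- function(pair) {
    if (is.null(model) || is(model, "AcquisitionModel")) model
    else model[[pair$psfId]]
  }
  d <- dim(dataset[[1]]$y0)
  H <- d[1]; W <- d[2]
  if (is.null(denoiser)) denoiser <- initDenoiser(spec, seed = seed)
  set.seed(as.integer(seed) + 1L)
  geom <- makeGeom(H, W, batchSize, denoiser@spec@depth)
  m <- zeroTree(denoiser@params); v <- zeroTree(denoiser@params)
  losses <- numeric(steps)
  Tn <- schedule@steps
  npix <- H * W
  for (s in seq_len(steps)) {
    idx <- sample.int(length(dataset), batchSize, replace = TRUE)
    ts <- sample.int(Tn, batchSize, replace = TRUE)
    ytv <- numeric(npix * batchSize)
    xv <- numeric(npix * batchSize)
    tgt <- numeric(npix * batchSize)
    gam <- numeric(batchSize)
    for (i in seq_len(batchSize)) {
      pair <- dataset[[idx[i]]]
      eps <- matrix(stats::rnorm(npix), H, W)
      gt <- guidanceTarget(schedule, modelFor(pair), pair, ts[i], eps, config)
      rows <- ((i - 1L) * npix + 1L):(i * npix)
      ytv[rows] <- gt$yt; xv[rows] <- pair$x; tgt[rows] <- gt$target
      gam[i] <- gt$gamma
    }
    fw <- denoiserFwd(denoiser, ytv, xv, gam, geom, keep = TRUE)
    resid <- fw$out - tgt
    losses[s] <- mean(resid^2)
    grads <- denoiserBwd(denoiser, 2 * resid / length(resid), geom, fw$cache)
    up <- adamTree(denoiser@params, grads, m, v, s, lr = lr)
    denoiser@params <- up$p; m <- up$m; v <- up$v
    if (logEvery > 0 && s %% logEvery == 0)
      message(sprintf("step %d/%d  loss %.4f", s, steps,
                      mean(losses[max(1, s - logEvery + 1):s])))
  }
  list(denoiser = denoiser, losses = losses)
}
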