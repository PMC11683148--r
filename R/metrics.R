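# Image quality metrics: PSNR, multi-scale SSIM (five dyadic scales, equal
# exponents summing to 1, 11x11 Gaussian window, sigma 1.5, K1 = 0.01,
# K2 = 0.03) and range-normalised RMSE, plus batch reports and the
# eta x regulariser ablation grid.

#' Peak signal-to-noise ratio
#'
#' PSNR = 20 log10(MAX_I) - 10 log10(MSE), in dB. Identical images return
#' \code{Inf} (the MSE = 0 sentinel). Scaling both images and MAX_I jointly
#' leaves the value unchanged.
#'
#' @param x,y images of identical shape.
#' @param maxValue MAX_I; defaults to the maximum of the reference y.
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, maxValue = max(y)) {
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  20 * log10(maxValue) - 10 * log10(mse)
}

#' Normalised root-mean-square error
#'
#' NRMSE = sqrt(MSE) / (y_max - y_min), normalised by the ground-truth
#' intensity range; invariant under a joint affine remap of both images.
#'
#' @param x estimate; \code{y} ground truth with non-constant values.
#' @param y ground truth.
#' @return dimensionless error >= 0; 0 iff the images are identical.
#' @export
nrmse <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  rng <- max(y) - min(y)
  if (rng <= 0) stop("constant ground truth: NRMSE undefined")
  sqrt(mean((x - y)^2)) / rng
}

gaussianWindow <- function(size = 11, sigma = 1.5) {
  ax <- seq_len(size) - (size + 1) / 2
  g <- exp(-ax^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# periodic filtering with the (small) window embedded in a full-size kernel
filterWith <- function(img, win) {
  k <- matrix(0, nrow(img), ncol(img))
  cy <- nrow(img) %/% 2 + 1L; cx <- ncol(img) %/% 2 + 1L
  h <- (nrow(win) - 1L) %/% 2L
  k[(cy - h):(cy + h), (cx - h):(cx + h)] <- win
  convolve2(img, k)
}

ssimComponents <- function(x, y, win, C1, C2) {
  mx <- filterWith(x, win); my <- filterWith(y, win)
  sxx <- filterWith(x * x, win) - mx^2
  syy <- filterWith(y * y, win) - my^2
  sxy <- filterWith(x * y, win) - mx * my
  C3 <- C2 / 2
  l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
  c <- (2 * sqrt(pmax(sxx, 0) * pmax(syy, 0)) + C2) / (sxx + syy + C2)
  s <- (sxy + C3) / (sqrt(pmax(sxx, 0) * pmax(syy, 0)) + C3)
  # anti-correlated structure is clamped at 0 so the fractional exponents
  # of the product form stay real
  list(l = mean(l), c = mean(c), s = max(mean(s), 0))
}

downsample2 <- function(img) {
  H <- (nrow(img) %/% 2) * 2; W <- (ncol(img) %/% 2) * 2
  img <- img[seq_len(H), seq_len(W), drop = FALSE]
  (img[seq(1, H, 2), seq(1, W, 2)] + img[seq(2, H, 2), seq(1, W, 2)] +
   img[seq(1, H, 2), seq(2, W, 2)] + img[seq(2, H, 2), seq(2, W, 2)]) / 4
}

#' Multi-scale structural similarity
#'
#' Product form over dyadic scales: luminance at the coarsest scale only,
#' contrast and structure at every scale, all exponents equal and summing
#' to 1. Images too small for the requested number of scales (the window
#' must fit after each halving) reduce the scale count with a warning.
#'
#' @param x,y images of identical shape, non-negative.
#' @param scales requested number of dyadic scales (default 5).
#' @param maxValue dynamic range L of the data (default: range of y).
#' @param windowSize,sigma Gaussian window parameters.
#' @return MS-SSIM in [0, 1] for non-negative inputs; 1 iff x == y.
#' @export
msSsim <- function(x, y, scales = 5, maxValue = max(y) - min(y),
                   windowSize = 11, sigma = 1.5) {
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  maxScales <- max(1L, floor(log2(min(dim(x)) / windowSize)) + 1L)
  if (maxScales < scales) {
    warning(sprintf("image too small for %d scales; using %d", scales,
                    maxScales))
    scales <- maxScales
  }
  w <- rep(1 / scales, scales)
  win <- gaussianWindow(windowSize, sigma)
  C1 <- (0.01 * maxValue)^2; C2 <- (0.03 * maxValue)^2
  val <- 1
  for (j in seq_len(scales)) {
    comp <- ssimComponents(x, y, win, C1, C2)
    val <- val * (comp$c^w[j]) * (comp$s^w[j])
    if (j == scales) val <- val * (comp$l^w[j])
    else { x <- downsample2(x); y <- downsample2(y) }
  }
  val
}

#' Evaluate a batch of restorations against ground truth
#'
#' @param preds list of restored images.
#' @param truths list of ground-truth images (same length and shapes).
#' @param maxValue PSNR/MS-SSIM dynamic range; default per-image truth range.
#' @return list with \code{perImage} (data.frame: psnr, msSsim, nrmse) and
#'   \code{summary} (mean and sd per metric).
#' @export
evaluateBatch <- function(preds, truths, maxValue = NULL) {
  stopifnot(length(preds) == length(truths))
  rows <- lapply(seq_along(preds), function(i) {
    mv <- if (is.null(maxValue)) max(truths[[i]]) else maxValue
    data.frame(image = i,
               psnr = psnr(preds[[i]], truths[[i]], maxValue = mv),
               msSsim = msSsim(preds[[i]], truths[[i]]),
               nrmse = nrmse(preds[[i]], truths[[i]]))
  })
  perImage <- do.call(rbind, rows)
  list(perImage = perImage,
       summary = data.frame(
         metric = c("psnr", "msSsim", "nrmse"),
         mean = c(mean(perImage$psnr), mean(perImage$msSsim),
                  mean(perImage$nrmse)),
         sd = c(stats::sd(perImage$psnr), stats::sd(perImage$msSsim),
                stats::sd(perImage$nrmse))))
}

#' Ablation grid over guidance strength and regularisers
#'
#' Restores every test record once per (eta, regulariser) cell with the
#' guided sampler and tabulates mean PSNR / MS-SSIM / NRMSE, mirroring the
#' role of the guidance-strength ablation: performance improves with eta up
#' to a point and degrades when the (approximate) gradient is over-weighted.
#'
#' @param records test records from [buildDataset()].
#' @param denoiser trained [Denoiser-class].
#' @param schedule a [DiffusionSchedule-class].
#' @param psfBank the PSF bank the records reference.
#' @param etas numeric vector of guidance strengths (0 = baseline DDPM).
#' @param regularisers character vector from c("none", "l1", "l2").
#' @param lambda regulariser weight.
#' @param rngSeed base seed.
#' @return data.frame with one row per (eta, regulariser) cell.
#' @export
runAblation <- function(records, denoiser, schedule, psfBank,
                        etas = c(0, 1, 5, 10, 25, 50),
                        regularisers = "none", lambda = 1e-3, rngSeed = 1) {
  grid <- expand.grid(eta = etas, regulariser = regularisers,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- guidanceConfig(eta = grid$eta[g],
                          regulariser = grid$regulariser[g],
                          lambda = if (grid$regulariser[g] == "none") 0
                                   else lambda)
    preds <- vector("list", length(records))
    truths <- vector("list", length(records))
    for (i in seq_along(records)) {
      r <- records[[i]]
      model <- acquisitionModel(psfBank$psfs[[r$psfId]],
                                photonScale = r$photons)
      xd <- toDiffusionRange(r$x)
      y0hat <- piSample(schedule, denoiser, model, xd, cfg,
                        rngSeed = rngSeed + i)
      preds[[i]] <- fromDiffusionRange(y0hat)
      truths[[i]] <- r$y0
    }
    ev <- evaluateBatch(preds, truths, maxValue = 1)
    out[[g]] <- data.frame(eta = grid$eta[g],
                           regulariser = grid$regulariser[g],
                           psnr = ev$summary$mean[1],
                           msSsim = ev$summary$mean[2],
                           nrmse = ev$summary$mean[3])
  }
  do.call(rbind, out)
}
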