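# Image acquisition model I = Poisson(s (h * y + b)) / s and the linear
# operator A (periodic convolution with the PSF) with its exact adjoint.
# Periodic boundaries keep A exactly linear and self-consistent with the
# FFT-built PSF; the adjoint is then correlation with the same kernel.

modelKernel <- function(model, shape) {
  k <- psfKernel(model@psf)
  if (!identical(dim(k), shape))
    stop("shape mismatch: PSF kernel is ", paste(dim(k), collapse = "x"),
         " but the image is ", paste(shape, collapse = "x"))
  k
}

#' Apply the linear blur operator A
#'
#' Noiseless, background-free periodic convolution of an image with the
#' model's PSF kernel.
#'
#' @param model an [AcquisitionModel-class].
#' @param y numeric matrix on the same lateral grid as the PSF.
#' @return numeric matrix h * y.
#' @export
applyA <- function(model, y) {
  if (!all(is.finite(y))) stop("image must be finite")
  convolve2(y, modelKernel(model, dim(y)))
}

#' Apply the adjoint operator A^T
#'
#' Correlation with the PSF kernel (convolution with the spatially flipped
#' kernel), same periodic boundary rule as [applyA()]; satisfies
#' \code{<A y, x> == <y, A^T x>} to round-off.
#'
#' @param model an [AcquisitionModel-class].
#' @param x numeric matrix.
#' @return numeric matrix A^T x.
#' @export
applyAAdjoint <- function(model, x) {
  if (!all(is.finite(x))) stop("image must be finite")
  convolve2(x, modelKernel(model, dim(x)), correlate = TRUE)
}

#' Simulate one acquisition: blur, background, Poisson photon noise
#'
#' x = Poisson(s (h * y + b)) / s with s = \code{photonScale}; the expected
#' value of x is h * y + b and its per-pixel variance is (h * y + b) / s
#' (Fano factor 1 in photon units).
#'
#' @param model an [AcquisitionModel-class].
#' @param y non-negative ground-truth image in intensity units.
#' @param rngSeed integer seed; the draw is reproducible.
#' @param modelId character tag stored in the returned pair.
#' @return An [ImagePair-class] holding the observation, the truth and the
#'   noiseless measurement h * y + b.
#' @export
acquire <- function(model, y, rngSeed, modelId = "acquisition") {
  if (any(y < 0)) stop("domain error: y must be >= 0 (Poisson rate)")
  noiseless <- applyA(model, y) + model@background
  rate <- model@photonScale * pmax(noiseless, 0)
  set.seed(as.integer(rngSeed))
  x <- matrix(stats::rpois(length(rate), lambda = rate) / model@photonScale,
              nrow(y), ncol(y))
  new("ImagePair", observation = x, truth = y, noiseless = noiseless,
      modelId = modelId)
}

#' Richardson-Lucy deconvolution baseline
#'
#' Standard multiplicative update
#' y_{k+1} = y_k . A^T(x / (A y_k + b)); flux-preserving under the periodic
#' boundary rule for a unit-sum kernel.
#'
#' @param x observed non-negative image.
#' @param psf a [PSFVolume-class] or 2-D kernel.
#' @param iterations number of updates, >= 1.
#' @param background scalar background b added inside the ratio.
#' @return restored image, same shape as x.
#' @export
richardsonLucy <- function(x, psf, iterations = 20, background = 0) {
  if (any(x < 0)) stop("x must be >= 0")
  if (iterations < 1) stop("iterations must be >= 1")
  k <- psfKernel(psf)
  if (sum(k) <= 0) stop("non-positive PSF sum")
  if (!identical(dim(k), dim(x))) stop("shape mismatch between x and PSF")
  y <- matrix(mean(x), nrow(x), ncol(x))
  eps <- .Machine$double.eps
  for (i in seq_len(iterations)) {
    est <- convolve2(y, k) + background
    y <- y * convolve2(x / pmax(est, eps), k, correlate = TRUE)
  }
  y
}
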