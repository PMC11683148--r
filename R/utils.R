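# FFT helpers. Everything user-facing uses the centred convention: the
# origin (zero frequency / PSF centre) sits at pixel (n %/% 2 + 1) on each
# axis; fftshift/ifftshift move between that and the FFT's corner-anchored
# layout.

rotIdx <- function(n, s) ((seq_len(n) - 1L + s) %% n) + 1L

# fftshift: corner origin (index 1) -> centre pixel (n %/% 2 + 1)
fftshift2 <- function(m) {
  d <- dim(m)
  m[rotIdx(d[1], -(d[1] %/% 2L)), rotIdx(d[2], -(d[2] %/% 2L)), drop = FALSE]
}

# ifftshift: centre pixel -> corner origin (inverse of fftshift2)
ifftshift2 <- function(m) {
  d <- dim(m)
  m[rotIdx(d[1], d[1] %/% 2L), rotIdx(d[2], d[2] %/% 2L), drop = FALSE]
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Centred FFT frequencies for n samples at pitch dx: spacing 1/(n dx).
kAxis <- function(n, dx) (seq_len(n) - (n %/% 2 + 1L)) / (n * dx)

# Centred spatial axis in the same units as dx.
xAxis <- function(n, dx) (seq_len(n) - (n %/% 2 + 1L)) * dx

#' Circular 2-D convolution with a centred kernel
#'
#' Periodic-boundary convolution via FFT. The kernel is given in the centred
#' convention (peak of a symmetric kernel at pixel \code{(n %/% 2 + 1)}), so
#' the output is not shifted.
#'
#' @param img numeric matrix.
#' @param kernel numeric matrix of the same shape.
#' @param correlate if TRUE compute correlation (convolution with the
#'   spatially flipped kernel), i.e. the adjoint of the convolution operator.
#' @return numeric matrix of the same shape.
#' @export
convolve2 <- function(img, kernel, correlate = FALSE) {
  if (!identical(dim(img), dim(kernel)))
    stop("image and kernel must share the same grid")
  K <- fft2(ifftshift2(kernel))
  if (correlate) K <- Conj(K)
  Re(ifft2(fft2(img) * K))
}

# Quadratic (parabolic) interpolation of an extremum location given three
# equally spaced samples y at x - 1, x, x + 1; returns the subpixel offset.
parabolicOffset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (abs(den) < .Machine$double.eps) return(0)
  0.5 * (ym1 - yp1) / den
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Map between intensity units and the diffusion value convention
#'
#' Images in (photon-normalised) intensity units, nominally [0, 1], are
#' affinely mapped to [-1, 1] at the diffusion boundary and back. Because
#' the blur kernel has unit sum, the linear measurement model is preserved
#' by this remap.
#'
#' @param img numeric matrix.
#' @return remapped matrix.
#' @export
toDiffusionRange <- function(img) 2 * img - 1

#' @rdname toDiffusionRange
#' @export
fromDiffusionRange <- function(img) (img + 1) / 2

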