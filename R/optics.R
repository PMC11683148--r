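# Pupil -> OTF -> PSF chain.
#
# The pupil Q(m) = A(m) exp(i phi(m)) is a complex field over the lateral
# k-grid, zero outside the aperture |k_perp| <= NA / lambda. The optical
# transfer function is the autocorrelation of the pupil, C(K) =
# sum_m Q(m + K) Q*(m), computed via FFT (Wiener-Khinchin). The inverse
# transform of C is |FT(Q)|^2 / N: the non-negative per-wavelength intensity
# PSF. Widefield image formation multiplies the excitation and emission
# intensity PSFs; confocal detection additionally masks the emission
# amplitude with the pinhole disk in the image plane (equivalently, convolves
# the disk's Fourier kernel with the emission pupil).
#
# Defocus: the axial wavevector on the spherical cap is
# k_z = sqrt((n/lambda)^2 - k_perp^2); plane z carries the extra pupil phase
# exp(2 pi i k_z z). The focal plane is the central z slice.

# lateral k^2 grid (cycles/um)^2 for a config, plus spacing
lateralKGrid <- function(config) {
  ny <- config@gridShape[2]; nx <- config@gridShape[3]
  dx <- config@pixelSizeXY
  ky <- kAxis(ny, dx); kx <- kAxis(nx, dx)
  list(k2 = outer(ky^2, kx^2, `+`), dk = c(1 / (ny * dx), 1 / (nx * dx)))
}

#' Build the complex pupil function of one wavelength
#'
#' Circular (spherical-cap) amplitude support of radius NA/lambda in the
#' lateral k-plane; the phase inside the aperture is the supplied aberration
#' phase (zero for an ideal system).
#'
#' @param config an [OpticalConfig-class].
#' @param wavelength wavelength in nanometres (usually \code{lambdaEx} or
#'   \code{lambdaEm} of the config).
#' @param aberrationPhase optional numeric matrix (ny x nx, radians) on the
#'   same k-grid; default zero everywhere.
#' @return A [PupilField-class].
#' @examples
#' cfg <- opticalConfig(0.8, 488, 520, gridShape = c(1, 64, 64),
#'                      pixelSizeXY = 0.05)
#' p <- makePupil(cfg, 520)
#' @export
makePupil <- function(config, wavelength, aberrationPhase = NULL) {
  stopifnot(is(config, "OpticalConfig"))
  validObject(config)
  if (wavelength <= 0) stop("wavelength must be > 0")
  lam <- wavelength * 1e-3                      # nm -> um
  kg <- lateralKGrid(config)
  kmax <- config@numericalAperture / lam        # aperture radius, cycles/um
  inside <- kg$k2 <= kmax^2
  # grid must resolve the aperture: at least 3 samples across the diameter
  ny <- config@gridShape[2]
  acrossRow <- sum(inside[ny %/% 2 + 1L, ])
  if (acrossRow < 3L)
    stop("sampling error: pupil support is fewer than 3 samples across; ",
         "enlarge the grid or the pixel size")
  A <- matrix(0, nrow(inside), ncol(inside))
  A[inside] <- 1
  if (!is.null(aberrationPhase)) {
    if (!identical(dim(aberrationPhase), dim(A)))
      stop("aberrationPhase must be defined on the same k-grid")
    Q <- A * exp(1i * aberrationPhase)
    Q[!inside] <- 0 + 0i
  } else {
    Q <- A + 0i
  }
  new("PupilField", values = Q, kSpacing = kg$dk, wavelength = wavelength)
}

# Pupil with the defocus phase of plane z (um) applied.
pupilAtZ <- function(pupil, config, z) {
  if (z == 0) return(pupil)
  lam <- pupil@wavelength * 1e-3
  kg <- lateralKGrid(config)
  kz2 <- (config@refractiveIndex / lam)^2 - kg$k2
  kz <- sqrt(pmax(kz2, 0))
  Q <- pupil@values * exp(2i * pi * kz * z)
  Q[Mod(pupil@values) == 0] <- 0 + 0i
  new("PupilField", values = Q, kSpacing = pupil@kSpacing,
      wavelength = pupil@wavelength)
}

#' Optical transfer function as the autocorrelation of the pupil
#'
#' Computes C(K) = sum_m Q(m + K) Q*(m) on the (uniform, periodic) k-grid by
#' FFT. The output lives on the same grid with the same spacing; since the
#' autocorrelation support is twice the pupil diameter, the pupil should
#' occupy less than half the grid for an alias-free OTF.
#'
#' @param pupil a [PupilField-class].
#' @return An [OTF-class].
#' @export
otfFromPupil <- function(pupil) {
  stopifnot(is(pupil, "PupilField"))
  if (length(pupil@kSpacing) != 2L || any(!is.finite(pupil@kSpacing)))
    stop("unsupported grid: pupil must live on a uniform k-grid")
  q <- ifftshift2(pupil@values)
  Fq <- fft2(q)
  # Wiener-Khinchin: ifft(|F|^2)[K] = sum_m q[m + K] conj(q[m])
  C <- fftshift2(ifft2(Fq * Conj(Fq)))
  new("OTF", values = C, kSpacing = pupil@kSpacing)
}

#' Inverse Fourier transform of an OTF
#'
#' Returns u = FT(C)/N in the centred convention. For an OTF built as a pupil
#' autocorrelation this equals |FT(Q)|^2 / N: the real, non-negative
#' per-wavelength intensity PSF (Wiener-Khinchin). Under this normalisation
#' Parseval reads sum |u|^2 = sum |C|^2 / N.
#'
#' @param otf an [OTF-class].
#' @return complex matrix (real up to round-off for Hermitian C), centred.
#' @export
amplitudePSF <- function(otf) {
  stopifnot(is(otf, "OTF"))
  fftshift2(fft2(ifftshift2(otf@values))) / length(otf@values)
}

# real-space emission amplitude field u_amp = FT(Q)/sqrt(N), centred;
# |u_amp|^2 equals Re(amplitudePSF(otfFromPupil(pupil))) exactly.
amplitudeFieldFromPupil <- function(pupil) {
  fftshift2(fft2(ifftshift2(pupil@values))) / sqrt(length(pupil@values))
}

# per-wavelength intensity PSF of one z plane through the OTF route
intensitySlice <- function(pupil, config, z) {
  pz <- pupilAtZ(pupil, config, z)
  u <- amplitudePSF(otfFromPupil(pz))
  pmax(Re(u), 0)
}

zPlanes <- function(config) {
  nz <- config@gridShape[1]
  xAxis(nz, config@pixelSizeZ)
}

normalisePSF <- function(h, config, mode) {
  s <- sum(h)
  if (s <= 0) stop("degenerate PSF: non-positive total intensity")
  new("PSFVolume", values = h / s,
      pixelSize = c(config@pixelSizeZ, config@pixelSizeXY, config@pixelSizeXY),
      mode = mode)
}

#' Widefield point-spread function
#'
#' h(x, y, z) = i_ex(x, y, z) * i_em(x, y, z), the product of the excitation
#' and emission intensity PSFs (the Airy diffraction pattern for an ideal
#' circular aperture), normalised to unit sum over the simulated volume.
#'
#' @param config an [OpticalConfig-class].
#' @param aberrationPhase optional aberration phase matrix passed to both
#'   pupils.
#' @return A [PSFVolume-class] with \code{mode = "widefield"}.
#' @examples
#' cfg <- opticalConfig(0.9, 500, 500, gridShape = c(1, 128, 128),
#'                      pixelSizeXY = 0.04)
#' h <- widefieldPSF(cfg)
#' sum(psfValues(h))  # 1
#' @export
widefieldPSF <- function(config, aberrationPhase = NULL) {
  pEx <- makePupil(config, config@lambdaEx, aberrationPhase)
  pEm <- makePupil(config, config@lambdaEm, aberrationPhase)
  zs <- zPlanes(config)
  d <- config@gridShape
  h <- array(0, dim = d)
  for (iz in seq_along(zs)) {
    h[iz, , ] <- intensitySlice(pEx, config, zs[iz]) *
                 intensitySlice(pEm, config, zs[iz])
  }
  normalisePSF(h, config, "widefield")
}

#' Binary pinhole transmission mask
#'
#' T(x, y) = 1 where x^2 + y^2 <= R^2 on the lateral image grid (pixel-centre
#' inclusion, no anti-aliasing). A radius below half a pixel degenerates to
#' the single centre pixel, with a warning.
#'
#' @param config an [OpticalConfig-class] with finite \code{pinholeRadius}.
#' @return numeric ny x nx matrix of 0/1.
#' @export
pinholeMask <- function(config) {
  R <- config@pinholeRadius
  if (!is.finite(R) || R <= 0)
    stop("pinholeRadius must be finite and > 0 for a pinhole mask")
  ny <- config@gridShape[2]; nx <- config@gridShape[3]
  dx <- config@pixelSizeXY
  r2 <- outer(xAxis(ny, dx)^2, xAxis(nx, dx)^2, `+`)
  Tm <- (r2 <= R^2) * 1
  if (R < dx / 2) {
    warning("pinhole radius below half a pixel: degenerate single-pixel mask")
    Tm[] <- 0
    Tm[ny %/% 2 + 1L, nx %/% 2 + 1L] <- 1
  }
  Tm
}

#' Confocal point-spread function
#'
#' The pinhole masks the emission amplitude in the image plane:
#' h = |T . u_em|^2 * i_ex, normalised. Multiplying the amplitude by the disk
#' T in the image plane is the pinhole operation expressed on the emission
#' pupil as a convolution with the disk's Fourier kernel; as R grows beyond
#' the field of view, T tends to 1 and h reduces exactly to the widefield PSF.
#'
#' @param config an [OpticalConfig-class] with finite \code{pinholeRadius}.
#' @param aberrationPhase optional aberration phase matrix.
#' @return A [PSFVolume-class] with \code{mode = "confocal"}.
#' @export
confocalPSF <- function(config, aberrationPhase = NULL) {
  if (!is.finite(config@pinholeRadius))
    stop("confocal PSF needs a finite pinholeRadius")
  pEx <- makePupil(config, config@lambdaEx, aberrationPhase)
  pEm <- makePupil(config, config@lambdaEm, aberrationPhase)
  Tm <- pinholeMask(config)
  zs <- zPlanes(config)
  d <- config@gridShape
  h <- array(0, dim = d)
  for (iz in seq_along(zs)) {
    uEm <- amplitudeFieldFromPupil(pupilAtZ(pEm, config, zs[iz]))
    h[iz, , ] <- Mod(Tm * uEm)^2 * intensitySlice(pEx, config, zs[iz])
  }
  normalisePSF(h, config, "confocal")
}

#' Lateral full width at half maximum of a PSF's focal plane
#'
#' Measured along the central row through the peak, with linear interpolation
#' at the half-maximum crossings.
#'
#' @param psf a [PSFVolume-class] or 2-D matrix.
#' @return FWHM in micrometres (pixels if a bare matrix is given).
#' @export
lateralFWHM <- function(psf) {
  if (is(psf, "PSFVolume")) {
    sl <- psfKernel(psf)
    dx <- psf@pixelSize[3]
  } else {
    sl <- psf; dx <- 1
  }
  cy <- nrow(sl) %/% 2 + 1L
  prof <- sl[cy, ]
  cx <- which.max(prof)
  half <- prof[cx] / 2
  # walk outwards to the first crossing on each side
  cross <- function(idx) {
    for (i in idx) {
      if (prof[i] < half) {
        lo <- prof[i]; hi <- prof[i - sign(i - cx)]
        frac <- (hi - half) / (hi - lo)
        return(abs(i - sign(i - cx) - cx) + frac)
      }
    }
    NA_real_
  }
  right <- cross(seq(cx + 1L, length(prof)))
  left <- cross(seq(cx - 1L, 1L))
  (right + left) * dx
}

#' First-zero radius of the focal-plane profile
#'
#' Locates the first local minimum of the centre-row profile through the peak
#' (the Airy dark ring for an ideal system), averaged over the four half-axes
#' of the two central rows/columns, with parabolic subpixel interpolation.
#'
#' @param psf a [PSFVolume-class].
#' @return radius in micrometres.
#' @export
firstZeroRadius <- function(psf) {
  stopifnot(is(psf, "PSFVolume"))
  sl <- psfKernel(psf)
  dx <- psf@pixelSize[3]
  cy <- nrow(sl) %/% 2 + 1L; cx <- ncol(sl) %/% 2 + 1L
  firstMin <- function(v) {
    for (i in 2:(length(v) - 1)) {
      if (v[i] <= v[i - 1] && v[i] < v[i + 1])
        return(i - 1 + parabolicOffset(v[i - 1], v[i], v[i + 1]))
    }
    NA_real_
  }
  arms <- list(sl[cy, cx:ncol(sl)], rev(sl[cy, 1:cx]),
               sl[cy:nrow(sl), cx], rev(sl[1:cy, cx]))
  r <- vapply(arms, firstMin, numeric(1))
  if (all(is.na(r))) stop("no local minimum found in the lateral profile")
  mean(r, na.rm = TRUE) * dx
}
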