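#' @import methods
NULL

#' Optical configuration of a simulated microscope
#'
#' Bundles the physical parameters of one (widefield or confocal) light
#' microscope: objective numerical aperture, excitation and emission
#' wavelengths, pinhole radius, immersion refractive index and the sampling
#' grid on which point-spread functions are rasterised.
#'
#' @slot numericalAperture numeric, dimensionless, in (0, 1.5]; must be
#'   strictly smaller than \code{refractiveIndex}.
#' @slot lambdaEx excitation wavelength in nanometres.
#' @slot lambdaEm emission wavelength in nanometres.
#' @slot pinholeRadius pinhole radius in micrometres; \code{Inf} means no
#'   pinhole (widefield detection).
#' @slot refractiveIndex immersion refractive index, dimensionless > 0.
#' @slot pixelSizeXY lateral pixel pitch in micrometres.
#' @slot pixelSizeZ axial step in micrometres.
#' @slot gridShape integer vector \code{c(nz, ny, nx)}.
#'
#' @seealso [opticalConfig()], [widefieldPSF()], [confocalPSF()]
#' @export
setClass("OpticalConfig",
  representation(
    numericalAperture = "numeric",
    lambdaEx = "numeric",
    lambdaEm = "numeric",
    pinholeRadius = "numeric",
    refractiveIndex = "numeric",
    pixelSizeXY = "numeric",
    pixelSizeZ = "numeric",
    gridShape = "integer"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  na <- object@numericalAperture
  if (length(na) != 1L || !is.finite(na) || na <= 0 || na > 1.5)
    msg <- c(msg, "numericalAperture must be a scalar in (0, 1.5]")
  if (length(na) == 1L && is.finite(na) && na >= object@refractiveIndex)
    msg <- c(msg, "numericalAperture must be < refractiveIndex (invalid aperture)")
  for (s in c("lambdaEx", "lambdaEm")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a positive scalar (nm)", s))
  }
  if (length(object@pinholeRadius) != 1L || is.na(object@pinholeRadius) ||
      object@pinholeRadius <= 0)
    msg <- c(msg, "pinholeRadius must be > 0 (Inf for widefield)")
  if (object@refractiveIndex <= 0) msg <- c(msg, "refractiveIndex must be > 0")
  if (object@pixelSizeXY <= 0 || object@pixelSizeZ <= 0)
    msg <- c(msg, "pixel sizes must be > 0")
  gs <- object@gridShape
  if (length(gs) != 3L || any(gs < 1L))
    msg <- c(msg, "gridShape must be three positive integers (nz, ny, nx)")
  if (length(msg)) msg else TRUE
})

#' Construct an OpticalConfig
#'
#' @param na numerical aperture (dimensionless).
#' @param lambdaEx,lambdaEm excitation/emission wavelengths in nanometres.
#' @param pinholeRadius pinhole radius in micrometres; \code{Inf} (default)
#'   means widefield detection.
#' @param refractiveIndex immersion refractive index (default 1.33).
#' @param pixelSizeXY lateral pixel pitch in micrometres.
#' @param pixelSizeZ axial step in micrometres.
#' @param gridShape integer vector \code{c(nz, ny, nx)}; \code{nz = 1} selects
#'   pure 2-D (focal plane) operation.
#' @return An [OpticalConfig-class] object.
#' @examples
#' cfg <- opticalConfig(na = 0.8, lambdaEx = 488, lambdaEm = 520,
#'                      pixelSizeXY = 0.05, gridShape = c(1, 64, 64))
#' @export
opticalConfig <- function(na, lambdaEx, lambdaEm, pinholeRadius = Inf,
                          refractiveIndex = 1.33, pixelSizeXY = 0.1,
                          pixelSizeZ = 0.25, gridShape = c(1L, 64L, 64L)) {
  new("OpticalConfig", numericalAperture = as.numeric(na),
      lambdaEx = as.numeric(lambdaEx), lambdaEm = as.numeric(lambdaEm),
      pinholeRadius = as.numeric(pinholeRadius),
      refractiveIndex = as.numeric(refractiveIndex),
      pixelSizeXY = as.numeric(pixelSizeXY),
      pixelSizeZ = as.numeric(pixelSizeZ),
      gridShape = as.integer(gridShape))
}

setMethod("show", "OpticalConfig", function(object) {
  cat(sprintf("OpticalConfig: NA=%.2f, lambda_ex=%g nm, lambda_em=%g nm\n",
              object@numericalAperture, object@lambdaEx, object@lambdaEm))
  cat(sprintf("  pinhole=%s um, n=%.2f, pixel=%g x %g um, grid=(%s)\n",
              if (is.finite(object@pinholeRadius))
                format(object@pinholeRadius) else "Inf (widefield)",
              object@refractiveIndex, object@pixelSizeXY, object@pixelSizeZ,
              paste(object@gridShape, collapse = ", ")))
})

#' Complex pupil field on the lateral k-space grid
#'
#' @slot values complex matrix (ny x nx), centred convention (zero frequency at
#'   pixel \code{(ny %/% 2 + 1, nx %/% 2 + 1)}).
#' @slot kSpacing reciprocal-micrometre spacing per lateral axis (ky, kx).
#' @slot wavelength wavelength in nanometres.
#' @export
setClass("PupilField",
  representation(values = "matrix", kSpacing = "numeric", wavelength = "numeric")
)

setValidity("PupilField", function(object) {
  if (!is.complex(object@values)) return("values must be complex")
  if (length(object@kSpacing) != 2L || any(object@kSpacing <= 0))
    return("kSpacing must be two positive numbers")
  TRUE
})

setMethod("show", "PupilField", function(object) {
  cat(sprintf("PupilField: %d x %d, lambda=%g nm, %d non-zero samples\n",
              nrow(object@values), ncol(object@values), object@wavelength,
              sum(Mod(object@values) > 0)))
})

#' Optical transfer function on the lateral k-space grid
#'
#' The autocorrelation of a pupil function, centred convention.
#'
#' @slot values complex matrix over the K grid.
#' @slot kSpacing reciprocal-micrometre spacing per axis; identical to the
#'   spacing of the pupil it was derived from (the autocorrelation support is
#'   twice as wide, so the pupil must occupy less than half the grid for an
#'   alias-free OTF).
#' @export
setClass("OTF",
  representation(values = "matrix", kSpacing = "numeric")
)

setMethod("show", "OTF", function(object) {
  cat(sprintf("OTF: %d x %d, |C| max %.3g at DC\n",
              nrow(object@values), ncol(object@values),
              max(Mod(object@values))))
})

#' Discretised point-spread function
#'
#' Non-negative, unit-sum PSF sampled on a (nz, ny, nx) grid; the focal plane
#' sits on the central z slice.
#'
#' @slot values numeric array of dim (nz, ny, nx), all >= 0, summing to 1.
#' @slot pixelSize micrometres per axis, (dz, dy, dx).
#' @slot mode "widefield" or "confocal".
#' @export
setClass("PSFVolume",
  representation(values = "array", pixelSize = "numeric", mode = "character")
)

setValidity("PSFVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-D array (nz, ny, nx)")
  if (any(object@values < -1e-12)) msg <- c(msg, "PSF values must be >= 0")
  if (abs(sum(object@values) - 1) > 1e-6)
    msg <- c(msg, "PSF must sum to 1")
  if (!object@mode %in% c("widefield", "confocal"))
    msg <- c(msg, "mode must be 'widefield' or 'confocal'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PSFVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("PSFVolume (%s): %d x %d x %d, peak %.3g, sum %.6f\n",
              object@mode, d[1], d[2], d[3], max(object@values),
              sum(object@values)))
})

#' @describeIn PSFVolume-class PSF voxel values
#' @param object,x a \code{PSFVolume}
#' @export
psfValues <- function(object) object@values

#' Extract the focal-plane 2-D convolution kernel of a PSF
#'
#' Takes the central z slice and renormalises it to unit sum, the kernel used
#' for 2-D image formation.
#'
#' @param psf a [PSFVolume-class] (or a plain numeric matrix, returned
#'   renormalised).
#' @return numeric matrix with sum 1.
#' @export
psfKernel <- function(psf) {
  k <- if (is(psf, "PSFVolume")) {
    v <- psf@values
    v[dim(v)[1] %/% 2 + 1, , ]
  } else {
    as.matrix(psf)
  }
  s <- sum(k)
  if (s <= 0) stop("PSF kernel has non-positive sum")
  k / s
}

#' Image acquisition model I = Poisson(s (h * y + b)) / s
#'
#' @slot psf the [PSFVolume-class] (or 2-D kernel matrix) h.
#' @slot background scalar (or image) b >= 0, in the same intensity units as y.
#' @slot photonScale photons per unit intensity, > 0.
#' @slot gaussianOffset xi >= 0: mean and variance of the Gaussian surrogate
#'   for the measurement noise, used only by the guidance term.
#' @export
setClass("AcquisitionModel",
  representation(psf = "ANY", background = "numeric", photonScale = "numeric",
                 gaussianOffset = "numeric")
)

setValidity("AcquisitionModel", function(object) {
  msg <- character()
  if (any(object@background < 0)) msg <- c(msg, "background must be >= 0")
  if (length(object@photonScale) != 1L || object@photonScale <= 0)
    msg <- c(msg, "photonScale must be a positive scalar")
  if (object@gaussianOffset < 0) msg <- c(msg, "gaussianOffset must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionModel
#'
#' @param psf a [PSFVolume-class] or 2-D kernel matrix.
#' @param background scalar background b >= 0 (intensity units).
#' @param photonScale expected photons per unit intensity.
#' @param gaussianOffset xi for the Gaussian noise surrogate (guidance only).
#' @export
acquisitionModel <- function(psf, background = 0, photonScale = 1000,
                             gaussianOffset = 0) {
  new("AcquisitionModel", psf = psf, background = as.numeric(background),
      photonScale = as.numeric(photonScale),
      gaussianOffset = as.numeric(gaussianOffset))
}

setMethod("show", "AcquisitionModel", function(object) {
  cat(sprintf("AcquisitionModel: photonScale=%g, background=%g, xi=%g\n",
              object@photonScale, object@background[1], object@gaussianOffset))
})

#' Degraded observation / ground truth image pair
#'
#' @slot observation degraded image x (photon-normalised intensity units).
#' @slot truth ground-truth object y0 in [0, 1].
#' @slot noiseless the noiseless measurement h * y0 + b (same units as x).
#' @slot modelId character tag of the acquisition model used.
#' @export
setClass("ImagePair",
  representation(observation = "matrix", truth = "matrix", noiseless = "matrix",
                 modelId = "character")
)

setValidity("ImagePair", function(object) {
  if (!identical(dim(object@observation), dim(object@truth)))
    return("observation and truth must have identical shape")
  if (!all(is.finite(object@observation)) || !all(is.finite(object@truth)))
    return("images must be finite")
  TRUE
})

setMethod("show", "ImagePair", function(object) {
  d <- dim(object@truth)
  cat(sprintf("ImagePair: %d x %d, model '%s', obs range [%.3g, %.3g]\n",
              d[1], d[2], object@modelId, min(object@observation),
              max(object@observation)))
})

#' Diffusion variance schedule
#'
#' Per-timestep quantities of the forward noising chain: beta_t, alpha_t =
#' 1 - beta_t, gamma_t = prod_{s<=t} alpha_s and the sampling variance
#' sigma_t^2 (either beta_t or the posterior variance beta-tilde_t).
#'
#' @slot steps number of timesteps T.
#' @slot beta,alpha,gamma,sigma2 numeric vectors of length T.
#' @slot kind "linear" or "cosine".
#' @slot sigmaChoice "beta" (upper bound) or "betaTilde" (lower bound).
#' @export
setClass("DiffusionSchedule",
  representation(steps = "integer", beta = "numeric", alpha = "numeric",
                 gamma = "numeric", sigma2 = "numeric", kind = "character",
                 sigmaChoice = "character")
)

setValidity("DiffusionSchedule", function(object) {
  msg <- character()
  Tn <- object@steps
  if (Tn < 1L) msg <- c(msg, "steps must be >= 1")
  for (s in c("beta", "alpha", "gamma", "sigma2"))
    if (length(slot(object, s)) != Tn)
      msg <- c(msg, sprintf("%s must have length T", s))
  if (any(object@beta < 0) || any(object@beta >= 1))
    msg <- c(msg, "beta must lie in [0, 1)")
  if (max(abs(object@alpha - (1 - object@beta))) > 1e-12)
    msg <- c(msg, "alpha must equal 1 - beta")
  g <- object@gamma
  if (max(abs(g - cumprod(object@alpha))) > 1e-9)
    msg <- c(msg, "gamma must be the cumulative product of alpha")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiffusionSchedule", function(object) {
  cat(sprintf(
    "DiffusionSchedule (%s): T=%d, beta in [%.2g, %.2g], gamma_T=%.3g (%s)\n",
    object@kind, object@steps, min(object@beta), max(object@beta),
    object@gamma[object@steps], object@sigmaChoice))
})

#' @describeIn DiffusionSchedule-class number of timesteps
#' @param object a \code{DiffusionSchedule}
#' @export
nSteps <- function(object) object@steps

#' Signal-retention gamma_t of a schedule (gamma_0 := 1)
#'
#' @param schedule a [DiffusionSchedule-class].
#' @param t timestep in 0..T.
#' @return gamma_t; \code{t = 0} returns 1.
#' @export
gammaAt <- function(schedule, t) {
  stopifnot(all(t >= 0), all(t <= schedule@steps))
  ifelse(t == 0, 1, schedule@gamma[pmax(t, 1L)])
}

#' Physics-guidance configuration
#'
#' @slot eta guidance strength (the annealed gradient has L2 norm
#'   eta * sqrt(gamma_t)); 0 disables guidance.
#' @slot xi Gaussian measurement-noise offset (mean = variance); 0 selects the
#'   noiseless-target variant where the residual is x-tilde - A y_t.
#' @slot regulariser "none", "l1" or "l2".
#' @slot lambda regulariser weight lambda_t: scalar (constant in t) or a
#'   vector of length T.
#' @slot noiselessTarget logical: training uses the retained noiseless
#'   measurement instead of x - xi.
#' @export
setClass("GuidanceConfig",
  representation(eta = "numeric", xi = "numeric", regulariser = "character",
                 lambda = "numeric", noiselessTarget = "logical")
)

setValidity("GuidanceConfig", function(object) {
  msg <- character()
  if (!is.finite(object@eta) || object@eta < 0)
    msg <- c(msg, "eta must be finite and >= 0")
  if (object@xi < 0) msg <- c(msg, "xi must be >= 0")
  if (!object@regulariser %in% c("none", "l1", "l2"))
    msg <- c(msg, "regulariser must be 'none', 'l1' or 'l2'")
  if (any(object@lambda < 0)) msg <- c(msg, "lambda must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a GuidanceConfig
#'
#' @param eta guidance strength (default 10).
#' @param xi Gaussian noise offset (default 0: noiseless-target variant).
#' @param regulariser "none", "l1" or "l2".
#' @param lambda regulariser weight (scalar or length-T vector).
#' @param noiselessTarget use the retained noiseless measurement in training.
#' @export
guidanceConfig <- function(eta = 10, xi = 0, regulariser = "none",
                           lambda = 0, noiselessTarget = TRUE) {
  new("GuidanceConfig", eta = as.numeric(eta), xi = as.numeric(xi),
      regulariser = match.arg(regulariser, c("none", "l1", "l2")),
      lambda = as.numeric(lambda), noiselessTarget = isTRUE(noiselessTarget))
}

setMethod("show", "GuidanceConfig", function(object) {
  cat(sprintf("GuidanceConfig: eta=%g, xi=%g, regulariser=%s, lambda=%g\n",
              object@eta, object@xi, object@regulariser, object@lambda[1]))
})

#' Denoiser architecture specification
#'
#' Contract for the conditional epsilon-prediction U-Net: encoder/decoder with
#' \code{depth} resolution levels, constant \code{baseChannels} feature width,
#' instance normalisation, skip connections and bilinear upsampling; the
#' continuous noise level gamma_t enters through a sinusoidal embedding.
#'
#' @slot depth number of resolution levels (>= 1).
#' @slot baseChannels feature channels per level.
#' @slot inChannels input channels (2: y_t concatenated with x).
#' @slot embDim dimension of the sinusoidal gamma embedding.
#' @export
setClass("DenoiserSpec",
  representation(depth = "integer", baseChannels = "integer",
                 inChannels = "integer", embDim = "integer")
)

setValidity("DenoiserSpec", function(object) {
  if (object@depth < 1L) return("depth must be >= 1")
  if (object@baseChannels < 1L) return("baseChannels must be >= 1")
  if (object@embDim < 2L || object@embDim %% 2L != 0L)
    return("embDim must be an even integer >= 2")
  TRUE
})

#' Construct a DenoiserSpec
#' @param depth resolution levels (default 3).
#' @param baseChannels feature width (default 32).
#' @param inChannels input channels (default 2).
#' @param embDim gamma embedding dimension (default 64).
#' @export
denoiserSpec <- function(depth = 3, baseChannels = 32, inChannels = 2,
                         embDim = 64) {
  new("DenoiserSpec", depth = as.integer(depth),
      baseChannels = as.integer(baseChannels),
      inChannels = as.integer(inChannels), embDim = as.integer(embDim))
}

setMethod("show", "DenoiserSpec", function(object) {
  cat(sprintf("DenoiserSpec: depth=%d, channels=%d, in=%d, embDim=%d\n",
              object@depth, object@baseChannels, object@inChannels,
              object@embDim))
})
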