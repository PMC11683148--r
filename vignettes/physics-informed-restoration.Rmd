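---
title: "Physics-informed diffusion restoration of light micrographs"
author: "pidiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed diffusion restoration of light micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pidiff)
```

## The problem

A fluorescence micrograph is not the object: it is the object convolved with
the microscope's point-spread function (PSF), offset by background, and
corrupted by photon-counting noise,

$$ I = \phi\big(h \ast y + b\big), $$

where $y$ is the object, $h$ the PSF, $b$ a background and $\phi$ Poisson
noise. `pidiff` implements both sides of this equation: a computed-optics
simulator that produces $h$ and degraded observations, and a conditioned
denoising diffusion probabilistic model (DDPM) whose training loss and
sampler are *guided* by the same forward model, so that reconstructions are
pulled toward the set of images consistent with the measurement. A
Richardson–Lucy deconvolution baseline and PSNR / MS-SSIM / NRMSE metrics
complete the toolkit.

## The optical forward model

The pupil of one wavelength $\lambda$ is a complex field over the lateral
frequency plane,

$$ Q(\mathbf m) = A(\mathbf m)\, e^{i\varphi(\mathbf m)}, $$

with a hard circular amplitude $A$ of radius $\mathrm{NA}/\lambda$ and an
aberration phase $\varphi$ (zero for an ideal system; a user-supplied field
otherwise — parametric aberration models such as Zernike expansions are out
of scope). The optical transfer function is the autocorrelation of the
pupil,

$$ C(\mathbf K) = \int Q\!\left(\mathbf m + \tfrac{\mathbf K}{2}\right)
   Q^\ast\!\left(\mathbf m - \tfrac{\mathbf K}{2}\right) d\mathbf m, $$

computed by FFT on the periodic grid. By the Wiener–Khinchin identity the
inverse transform of $C$ is $|\mathcal F(Q)|^2/N$ — the non-negative
*intensity* PSF of that wavelength. The widefield PSF multiplies excitation
and emission intensities,

$$ h = i_{\mathrm{ex}} \cdot i_{\mathrm{em}}, $$

which for an ideal circular aperture at $\lambda_{ex} = \lambda_{em}$
reproduces the squared Airy intensity $[2 J_1(v)/v]^4$ with its first dark
ring at $0.61\,\lambda/\mathrm{NA}$ — the oracle the test suite checks to
within 3 % on a Nyquist-sampled grid.

Confocal detection adds a pinhole of radius $R$ in the image plane. We model
it as the disk mask applied to the emission *amplitude* in the image plane,
$u'_{em} = T \cdot u_{em}$, which in the conjugate pupil plane is exactly the
convolution of the emission pupil with the disk's Fourier kernel. Two limits
pin the implementation down: as $R$ grows beyond the field of view, $T
\equiv 1$ and the confocal PSF reduces *identically* to the widefield PSF;
a sub-Airy pinhole (below the half-maximum radius, $R \lesssim 0.17$ Airy
units) strictly narrows the lateral FWHM; and the L2 distance to the
widefield PSF decreases monotonically in $R$. We note that reading the
pinhole operation instead as a literal lateral convolution of the disk with
the amplitude field does not reproduce the first limit (convolution with an
all-ones mask is not the identity), which is why the image-plane masking
reading is used.

Defocus enters through the spherical-cap axial wavevector
$k_z = \sqrt{(n/\lambda)^2 - k_\perp^2}$: plane $z$ multiplies the pupil by
$e^{2\pi i k_z z}$. For 2-D work (`nz = 1`, the default) only the focal
slice is rendered; 3-D stacks place the focal plane on the central slice.
PSFs are normalised to unit sum over the simulated volume, so the blur
operator conserves flux and preserves constants.

```{r psf}
cfg <- opticalConfig(na = 0.9, lambdaEx = 488, lambdaEm = 520,
                     pixelSizeXY = 0.04, gridShape = c(1, 128, 128))
h <- widefieldPSF(cfg)
c(sum = sum(psfValues(h)), fwhm_um = lateralFWHM(h))
```

## Acquisition, units, and the linear operator

`acquisitionModel()` bundles a PSF, a scalar background $b$ (default 0 for
synthetic data; the model includes it but no canonical value exists), and a
photon scale $s$ (expected photons per unit intensity). `applyA()` is
periodic (circular) convolution with the unit-sum kernel via FFT — the
boundary rule that makes $A$ exactly linear, self-consistent with the
FFT-built PSF, and makes the adjoint `applyAAdjoint()` plain correlation;
the test suite checks $\langle Ay, x\rangle = \langle y, A^T x\rangle$ to
$10^{-8}$ and compares against a dense brute-force operator. `acquire()`
draws $x = \mathrm{Pois}(s\,(h\ast y + b))/s$, so the per-pixel variance
equals the mean in photon units (Fano factor 1).

Intensities live in $[0,1]$; the diffusion model works in the standard DDPM
value convention $[-1,1]$ via `toDiffusionRange()`. Because the kernel has
unit sum, $A$ commutes with the affine remap and the linear measurement
model holds unchanged in diffusion coordinates.

## The diffusion model

The forward chain adds Gaussian noise with variances $\beta_1..\beta_T$;
with $\alpha_t = 1-\beta_t$ and $\gamma_t = \prod_{s\le t}\alpha_s$ the
closed form is $y_t = \sqrt{\gamma_t}\,y_0 + \sqrt{1-\gamma_t}\,\epsilon$.
The exact posterior $q(y_{t-1}\mid y_t, y_0)$ is Gaussian with mean
$\tilde\mu = \frac{\sqrt{\gamma_{t-1}}\beta_t}{1-\gamma_t} y_0 +
\frac{\sqrt{\alpha_t}(1-\gamma_{t-1})}{1-\gamma_t} y_t$ and variance
$\tilde\beta_t$; the suite verifies it against numerical Bayes on a scalar
problem to $10^{-6}$. A network $\epsilon_\theta(y_t, x, \gamma_t)$ predicts
the noise given the noised state, the observation $x$ (channel-concatenated)
and the *continuous* signal level $\gamma_t$ (sinusoidally embedded), and is
trained with the conditioned simple loss
$\lVert\epsilon - \epsilon_\theta\rVert^2$.

Defaults: linear schedule, $\beta \in [10^{-4}, 0.02]$ at $T = 1000$ (the
cited DDPM convention), scaled proportionally for shorter chains (we use
$\beta \in [10^{-3}, 0.2]$, $T = 100$ throughout the desk-scale runs so that
$\gamma_T \approx 4\times10^{-5}$); sampling variance $\sigma_t^2 = \beta_t$
(the upper bound), with the posterior variance $\tilde\beta_t$ selectable.

## Physics-informed guidance

For the linear-Gaussian surrogate measurement model
$x = Ay + n,\; n \sim N(\xi, \xi I)$, the data-likelihood gradient is

$$ \nabla_{y_t} \log p(x\mid y_t) \approx
   \frac{A^T\!\big(x - \xi - A y_t\big)}{\xi^2}, $$

the ascent direction of the log-likelihood (equivalently the descent
direction of the quadratic data-fidelity term — the suite checks the sign
and the value against central finite differences). During training on
synthetic data the noiseless measurement $\tilde x = A y_0$ is retained and
replaces $x - \xi$; the $1/\xi^2$ prefactor is then irrelevant because the
gradient is *annealed*:

$$ \nu_t = \eta\,\frac{\sqrt{\gamma_t}}{\lVert g \rVert_2}, $$

so the scaled gradient has L2 norm exactly $\eta\sqrt{\gamma_t}$: guidance
is weak where the iterate is mostly noise and tightens as $t \to 0$. The
annealing normalisation makes the guidance scale-free, so $\xi$ only
matters when guiding against a noisy target at inference.

The physics-informed training loss regresses the network onto the *shifted*
noise,

$$ L = \big\lVert \epsilon + \sigma_t^2 g - \epsilon_\theta(y_t, x,
  \gamma_t) \big\rVert^2 , $$

(the factorisation constant set to 1), and the guided sampler shifts each
transition mean by $\sigma_t^2 g$ evaluated at the current iterate against
the observation, optionally minus $\sigma_t^2 \lambda_t \nabla R(y_t)$ for
an L1 or L2 regulariser ($R$ is *descended*: the shift must decrease
$\lVert Ay - x\rVert^2 + \lambda R$). $\lambda_t$ is constant by default.
With $\eta = 0$ and no regulariser, loss and sampler are bit-identical to
the conditioned DDPM — the baseline is the strict special case, and the
test suite asserts this at the level of training traces and sampling
trajectories. The default $\eta = 10$; an ablation helper (`runAblation()`)
exposes a grid over $\eta$ and regularisers. The model-prediction-dependent
approximation $p(x \mid y_t) \approx p(x \mid \hat y_0)$ is deliberately
not implemented: guidance must not create a learning signal through $g$.
Guidance is applied at every reverse step.

## The denoiser

The package has no deep-learning framework dependency: the conditional
U-Net is written in base R with explicit analytic gradients (im2col
gathers + BLAS matrix products), and the
backward pass is validated against central finite differences in the test
suite. The architecture is an encoder–decoder with `depth` (default 3)
resolution levels at a constant `baseChannels` (default 32) width: two
3×3-convolution blocks per level, instance normalisation, ReLU, the
$\gamma_t$ embedding projected into the first block of each level, 2×2
average-pool downsampling, factor-2 bilinear upsampling, and encoder–decoder
skip concatenation. Exact widths and block counts of the original
architecture are not published; these defaults are sized for CPU training.

Two numerical choices matter and are worth recording:

* **Residual paths.** Each level is wrapped in a residual connection
  (identity, or a learned 1×1 projection where the channel count changes).
  Instance normalisation removes the per-sample mean of every feature map;
  without an unnormalised path the network cannot respond to the DC
  component of $y_t$, and the reverse chain amplifies DC errors by
  $1/\sqrt{\gamma_T}$ (about 150 at our settings) — the sampler then drifts
  by tens of intensity units.
* **Clipped-$\hat y_0$ transitions.** The samplers form the transition mean
  through the implied clean image $\hat y_0 = (y_t -
  \sqrt{1-\gamma_t}\,\epsilon_\theta)/\sqrt{\gamma_t}$, clip it to $[-1,1]$,
  and take the exact posterior mean of $(\hat y_0, y_t)$ — algebraically
  identical to the direct $\epsilon$-parameterised mean when the clip is
  inactive, and the standard safeguard against accumulation of denoiser
  error along the chain (`clipDenoised = FALSE` disables it).

Training is plain stochastic gradient descent with Adam (learning rate
$10^{-3}$), per-sample $t \sim U\{1..T\}$ and $\epsilon \sim N(0, I)$,
mean-squared-error reduction over pixels and batch, fully seeded: two runs
with the same seed are bit-identical.

## Synthetic corpus

The generator emulates the acquisition conditions of a mixed simulated
corpus: per record a phantom (bars, points, disks, filaments, or a
Shepp–Logan-style head phantom with seeded rotation/shift jitter), a PSF
drawn from a bank with numerical aperture 0.4–1.0, excitation 320–400 nm,
emission 450–550 nm, pinhole radius 0.1–1000 µm and refractive index 1.33,
and an expected dose of 50, 500 or 5000 photons per unit intensity. The
pinhole range spans four decades, so it is sampled log-uniformly (the
sampling law is otherwise unstated); the wavelength ranges are read in
nanometres. PSFs are rendered on the image grid (32 px, 0.06 µm pitch — a
pitch at which every configuration in the ranges is both Nyquist-sampled
and alias-free). Noiseless measurements $\tilde x = A y_0$ are retained
with every record for the physics-informed loss, records regenerate
bit-identically from their manifest, and train/test corpora built from
different base seeds have disjoint phantom seeds.

What the phantoms do *not* emulate: natural-image statistics, real
subcellular texture, spatially varying PSFs, camera read noise or gain.
Passing the desk-scale tests therefore demonstrates that the machinery
learns and restores under its own forward model, not performance on real
micrographs.

## Desk-scale study and what it shows

The reproducible end-to-end run (`scripts/acceptance.R`, also mirrored in
the test suite) trains the 3-level / 32-channel denoiser on 200 synthetic
pairs of 32×32 phantoms at $T = 100$ for 2000 Adam steps (batch 4), about
seven minutes on one CPU core. It checks that (a) a single-image overfit
fixture drops its smoothed training loss by more than an order of
magnitude, (b) the mean PSNR of guided restorations — the per-pixel mean
over 8 samples, which is also the package's posterior-mean estimate —
exceeds the mean PSNR of the degraded inputs on a held-out 12-image test
corpus, and (c) the per-pixel standard-deviation map over those samples is
a non-trivial, spatially structured uncertainty estimate. Problem sizes
were chosen once for a single-core desk budget; at this scale the margin in
(b) is modest (about 1–2 dB) and concentrated in the structured phantoms —
sparse point phantoms start from a high degraded PSNR that a stochastic
sampler only matches.

## Metrics

`psnr()` ($20\log_{10}\mathrm{MAX} - 10\log_{10}\mathrm{MSE}$; identical
images report `Inf`), `nrmse()` ($\sqrt{\mathrm{MSE}}$ over the
ground-truth range), and `msSsim()` — the five-scale product form with
luminance only at the coarsest scale, equal exponents summing to 1, an
11×11 Gaussian window ($\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$),
dyadic average-pool downsampling, periodic-boundary filtering, and the
anti-correlated structure term clamped at zero so fractional exponents stay
real. Images too small for five scales reduce the scale count with a
warning; metrics default to the $[0,1]$ intensity convention.

## Limitations

* The pinhole model is coherent image-plane masking; partially coherent and
  polarisation-resolved (vectorial-component) treatments are out of scope.
* The PSF is spatially invariant and must be supplied at restoration time;
  no blind/implicit operator estimation is attempted.
* 16-bit PNG output is unavailable (the installed PNG bindings write 8-bit);
  use 32-bit float TIFF or CSV for lossless round-trips.
* Desk-scale training (minutes, not GPU-days) bounds the restoration
  quality; the acceptance run demonstrates the mechanics, not
  state-of-the-art image quality.
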