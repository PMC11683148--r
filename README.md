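# pidiff

Physics-informed diffusion restoration of light-microscopy images, in R.

Fluorescence micrographs are degraded copies of the specimen: the object
`y` is blurred by the microscope's point-spread function `h`, offset by a
background `b`, and counted as photons,

```
I = Poisson( s · (h ∗ y + b) ) / s .
```

`pidiff` is for people who want to simulate this forward model and to study
or apply measurement-consistent diffusion restoration on top of it. It
implements:

* **Computed optics** — pupil function `Q(m) = A(m) e^{iφ(m)}`, optical
  transfer function as the pupil autocorrelation
  `C(K) = ∫ Q(m + K/2) Q*(m − K/2) dm` (FFT, Wiener–Khinchin), widefield
  PSF `h = i_ex · i_em` (the Airy pattern `[2J₁(v)/v]⁴` for an ideal
  aperture), confocal pinhole masking, defocus via the spherical-cap
  `k_z = √((n/λ)² − k⊥²)`.
* **Acquisition** — the exactly linear blur operator `A` (periodic FFT
  convolution) with its adjoint, seeded Poisson acquisition, and a
  Richardson–Lucy deconvolution baseline.
* **Conditioned DDPM** — variance schedules, the closed-form forward
  process `y_t = √γ_t y₀ + √(1−γ_t) ε`, the exact posterior
  `q(y_{t−1}|y_t, y₀)`, the ε-prediction objective
  `‖ε − ε_θ(y_t, x, γ_t)‖²` and ancestral sampling.
* **Physics-informed guidance** — the data-likelihood gradient
  `g = Aᵀ(x − ξ − A y_t)/ξ²`, annealed to norm `η√γ_t`
  (`ν_t = η√γ_t / ‖g‖₂`, default `η = 10`); the guided training loss
  `‖ε + σ_t² g − ε_θ‖²` and the guided sampler whose transition mean is
  shifted by `σ_t² g` (optionally minus an L1/L2 regulariser gradient).
  With `η = 0` everything reduces bit-for-bit to the conditioned DDPM.
* **A self-contained denoiser** — a small conditional U-Net written in base
  R with explicit analytic gradients (validated against finite differences
  in the tests), Adam training, fully seeded.
* **Synthetic corpus** — random PSF banks (NA 0.4–1.0, excitation
  320–400 nm, emission 450–550 nm, pinhole 0.1–1000 µm, n = 1.33), phantom
  images (bars, points, disks, filaments, Shepp–Logan-style) with analytic
  structure metadata, and degraded/noiseless training pairs — no downloads.
* **Metrics** — PSNR, five-scale MS-SSIM, NRMSE, batch reports, and an
  `η × regulariser` ablation grid.

## Worked example

Simulate a widefield microscope, degrade a phantom, and deconvolve:

```r
library(pidiff)

cfg <- opticalConfig(na = 0.9, lambdaEx = 488, lambdaEm = 520,
                     pixelSizeXY = 0.04, gridShape = c(1, 64, 64))
h <- widefieldPSF(cfg)
h
#> PSFVolume (widefield): 1 x 64 x 64, peak 0.0344, sum 1.000000
lateralFWHM(h)        # 0.209 um
firstZeroRadius(h)    # 0.343 um; the Airy prediction 0.61*lambda/NA = 0.352 um

ph    <- makePhantom("disks", size = 64, n = 3, seed = 7)
model <- acquisitionModel(h, photonScale = 200)   # ~200 photons per unit intensity
pair  <- acquire(model, ph$image, rngSeed = 7)
rl    <- richardsonLucy(pair@observation, h, iterations = 30)

psnr(pair@observation, ph$image, maxValue = 1)    # 23.99 dB (degraded)
psnr(rl, ph$image, maxValue = 1)                  # 26.22 dB (Richardson-Lucy)
```

The PSF peak sits at the expected diffraction scale (first dark ring within
3 % of `0.61 λ/NA`), the acquisition is reproducible from its seed, and the
baseline deconvolution recovers ~2 dB.

Training and guided restoration at desk scale:

```r
bank   <- samplePSFBank(8, seed = 1)
corpus <- buildDataset(200, bank, seed = 2)
sch    <- makeSchedule(100, betaRange = c(1e-3, 0.2))
fit    <- trainDenoiser(toDiffusionPairs(corpus$records), sch,
                        model = bankModels(bank), config = guidanceConfig(eta = 10),
                        pi = TRUE, spec = denoiserSpec(3, 32),
                        steps = 2000, batchSize = 4, seed = 3)

r   <- corpus$records[[1]]
mod <- acquisitionModel(bank$psfs[[r$psfId]], photonScale = r$photons)
ens <- restoreEnsemble(sch, fit$denoiser, mod, toDiffusionRange(r$x),
                       guidanceConfig(eta = 10), nSamples = 8, rngSeed = 4)
# ens$mean: the restoration (posterior-mean estimate)
# ens$sd:   the per-pixel uncertainty map over the 8 samples
```

A thin command-line front end over the same functions ships in
`inst/scripts/pi-ddpm` (`simulate-psf`, `degrade`, `make-dataset`, `train`,
`restore`, `evaluate`; every subcommand honours `--seed`).

## Package layout

| Area | Files |
| --- | --- |
| S4 classes and validity | `R/AllClasses.R` |
| Pupil / OTF / PSF optics | `R/optics.R` |
| Acquisition model, Richardson–Lucy | `R/acquisition.R` |
| Schedules, forward process, posterior, sampler | `R/diffusion.R` |
| Guidance gradient, PI loss, guided sampler | `R/guidance.R` |
| U-Net with explicit gradients | `R/denoiser.R`, `R/train.R` |
| Phantoms, PSF bank, corpus builder | `R/phantoms.R` |
| PSNR / MS-SSIM / NRMSE, ablation | `R/metrics.R` |
| Image and checkpoint I/O | `R/io.R` |
| Methods write-up | `vignettes/physics-informed-restoration.Rmd` |
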