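# Synthetic corpus: random microscope PSFs drawn from physically plausible
# parameter ranges, phantom ground-truth images with analytic structure
# metadata, and degraded observations produced by the acquisition model.

#' Default PSF parameter sampling ranges
#'
#' Numerical aperture 0.4-1.0, excitation wavelength 320-400 nm, emission
#' wavelength 450-550 nm, pinhole radius 0.1-1000 um (log-uniform over the
#' four decades), refractive index fixed at 1.33, focal plane centred.
#'
#' @return named list of ranges consumed by [samplePSFBank()].
#' @export
psfSamplingRanges <- function() {
  list(na = c(0.4, 1.0), lambdaEx = c(320, 400), lambdaEm = c(450, 550),
       pinhole = c(0.1, 1000), refractiveIndex = 1.33)
}

#' Sample a bank of random PSFs
#'
#' Each PSF gets independently drawn parameters (uniform in range; pinhole
#' log-uniform) and is rendered on the image grid. The parameter log is
#' returned alongside so each PSF is fully reproducible.
#'
#' @param n number of PSFs (>= 1).
#' @param seed integer seed.
#' @param ranges list as returned by [psfSamplingRanges()].
#' @param size lateral grid side in pixels.
#' @param pixelSize lateral pixel pitch in micrometres. The default 0.06 um
#'   keeps every configuration in the ranges both Nyquist-sampled (OTF
#'   cutoff 2 NA / lambda below the grid Nyquist rate) and alias-free on a
#'   32-pixel grid.
#' @return list with \code{psfs} (list of [PSFVolume-class]) and
#'   \code{params} (data.frame log: na, lambdaEx, lambdaEm, pinhole).
#' @export
samplePSFBank <- function(n, seed = 1, ranges = psfSamplingRanges(),
                          size = 32, pixelSize = 0.06) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  params <- data.frame(
    na = stats::runif(n, ranges$na[1], ranges$na[2]),
    lambdaEx = stats::runif(n, ranges$lambdaEx[1], ranges$lambdaEx[2]),
    lambdaEm = stats::runif(n, ranges$lambdaEm[1], ranges$lambdaEm[2]),
    pinhole = exp(stats::runif(n, log(ranges$pinhole[1]),
                               log(ranges$pinhole[2])))
  )
  psfs <- lapply(seq_len(n), function(i) {
    cfg <- opticalConfig(params$na[i], params$lambdaEx[i], params$lambdaEm[i],
                         pinholeRadius = params$pinhole[i],
                         refractiveIndex = ranges$refractiveIndex,
                         pixelSizeXY = pixelSize,
                         gridShape = c(1L, size, size))
    suppressWarnings(confocalPSF(cfg))
  })
  list(psfs = psfs, params = params)
}

# ---- phantoms -------------------------------------------------------------

drawDisk <- function(img, cy, cx, r, val) {
  n <- nrow(img)
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  img[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- val
  img
}

#' Generate a phantom ground-truth image
#'
#' Deterministic given the seed; values in [0, 1]; the analytic description
#' of the structures (coordinates, radii, endpoints) is returned as metadata
#' for downstream scoring.
#'
#' @param kind one of "bars", "points", "disks", "filaments", "shepp_logan".
#' @param size image side in pixels.
#' @param n number of structures (ignored for shepp_logan).
#' @param seed integer seed.
#' @return list with \code{image} (size x size matrix in [0, 1]) and
#'   \code{meta} (list describing the structures).
#' @examples
#' ph <- makePhantom("points", 32, n = 3, seed = 1)
#' sum(ph$image > 0) == 3
#' @export
makePhantom <- function(kind = c("bars", "points", "disks", "filaments",
                                 "shepp_logan"),
                        size = 32, n = 4, seed = 1) {
  kind <- match.arg(kind)
  if (size < 8) stop("degenerate size: need at least 8 pixels")
  set.seed(as.integer(seed))
  img <- matrix(0, size, size)
  meta <- list(kind = kind, size = size, seed = seed)
  if (kind == "points") {
    idx <- sample.int(size * size, n)
    vals <- stats::runif(n, 0.5, 1)
    img[idx] <- vals
    meta$coords <- cbind(row = (idx - 1L) %% size + 1L,
                         col = (idx - 1L) %/% size + 1L)
    meta$values <- vals
  } else if (kind == "bars") {
    bars <- vector("list", n)
    for (i in seq_len(n)) {
      horiz <- stats::runif(1) < 0.5
      w <- sample(1:3, 1)
      len <- sample(seq(size %/% 2, size - 2), 1)
      p0 <- sample(seq_len(size - w), 1)
      q0 <- sample(seq_len(size - len + 1), 1)
      val <- stats::runif(1, 0.5, 1)
      if (horiz) img[p0:(p0 + w - 1L), q0:(q0 + len - 1L)] <- val
      else img[q0:(q0 + len - 1L), p0:(p0 + w - 1L)] <- val
      bars[[i]] <- list(horizontal = horiz, width = w, length = len,
                        offset = p0, start = q0, value = val)
    }
    meta$bars <- bars
  } else if (kind == "disks") {
    disks <- vector("list", n)
    for (i in seq_len(n)) {
      r <- stats::runif(1, 2, max(3, size / 8))
      cy <- stats::runif(1, r + 1, size - r)
      cx <- stats::runif(1, r + 1, size - r)
      val <- stats::runif(1, 0.4, 1)
      img <- drawDisk(img, cy, cx, r, val)
      disks[[i]] <- list(cy = cy, cx = cx, r = r, value = val)
    }
    meta$disks <- disks
  } else if (kind == "filaments") {
    paths <- vector("list", n)
    occupied <- matrix(FALSE, size, size)
    for (i in seq_len(n)) {
      for (attempt in 1:50) {
        len <- sample(seq(size, 2L * size), 1)
        y <- stats::runif(1, 2, size - 1); x <- stats::runif(1, 2, size - 1)
        ang <- stats::runif(1, 0, 2 * pi)
        pts <- matrix(0L, len, 2)
        ok <- TRUE
        py <- y; px <- x
        for (s in seq_len(len)) {
          ang <- ang + stats::rnorm(1, 0, 0.25)
          py <- py + 0.7 * sin(ang); px <- px + 0.7 * cos(ang)
          if (py < 1 || py > size || px < 1 || px > size) { pts <- pts[seq_len(s - 1L), , drop = FALSE]; break }
          pts[s, ] <- c(round(py), round(px))
        }
        pts <- unique(pts[pts[, 1] > 0, , drop = FALSE])
        if (nrow(pts) < 4) next
        # keep filaments separated so each stays its own component
        pad <- occupied
        near <- FALSE
        for (j in seq_len(nrow(pts))) {
          ys <- max(1, pts[j, 1] - 1):min(size, pts[j, 1] + 1)
          xs <- max(1, pts[j, 2] - 1):min(size, pts[j, 2] + 1)
          if (any(occupied[ys, xs])) { near <- TRUE; break }
        }
        if (near) next
        val <- stats::runif(1, 0.6, 1)
        img[pts] <- val
        occupied[pts] <- TRUE
        paths[[i]] <- list(points = pts, value = val)
        ok <- TRUE
        break
      }
      if (is.null(paths[[i]]))
        stop("could not place ", n, " non-touching filaments on this grid")
    }
    meta$filaments <- paths
  } else { # shepp_logan
    # modified head phantom (ten ellipses, low-contrast interior), with a
    # small seeded rotation/shift for corpus variety
    E <- rbind(
      c(1.0, .69, .92, 0, 0, 0),
      c(-0.8, .6624, .8740, 0, -.0184, 0),
      c(-0.2, .1100, .3100, .22, 0, -18),
      c(-0.2, .1600, .4100, -.22, 0, 18),
      c(0.1, .2100, .2500, 0, .35, 0),
      c(0.1, .0460, .0460, 0, .1, 0),
      c(0.1, .0460, .0460, 0, -.1, 0),
      c(0.1, .0460, .0230, -.08, -.605, 0),
      c(0.1, .0230, .0230, 0, -.606, 0),
      c(0.1, .0230, .0460, .06, -.605, 0))
    rot <- stats::runif(1, -15, 15) * pi / 180
    shift <- stats::runif(2, -0.1, 0.1)
    ax <- seq(-1, 1, length.out = size)
    X <- outer(rep(1, size), ax) - shift[1]
    Y <- outer(ax, rep(1, size)) - shift[2]
    Xr <- cos(rot) * X + sin(rot) * Y
    Yr <- -sin(rot) * X + cos(rot) * Y
    for (i in seq_len(nrow(E))) {
      phi <- E[i, 6] * pi / 180
      xc <- Xr - E[i, 4]; yc <- Yr + E[i, 5]
      xp <- cos(phi) * xc + sin(phi) * yc
      yp <- -sin(phi) * xc + cos(phi) * yc
      img[(xp / E[i, 2])^2 + (yp / E[i, 3])^2 <= 1] <-
        img[(xp / E[i, 2])^2 + (yp / E[i, 3])^2 <= 1] + E[i, 1]
    }
    img <- clamp01(img)
    meta$rotation <- rot; meta$shift <- shift
  }
  img <- clamp01(img)
  if (all(img == 0)) stop("degenerate phantom: no structure generated")
  list(image = img, meta = meta)
}

#' Label 8-connected components of a binary mask
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
labelComponents <- function(mask) {
  mask <- mask > 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  H <- nrow(mask); W <- ncol(mask)
  for (start in which(mask & lab == 0L)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      y <- (p - 1L) %% H + 1L; x <- (p - 1L) %/% H + 1L
      for (dy in -1:1) for (dx in -1:1) {
        ny <- y + dy; nx <- x + dx
        if (ny < 1 || ny > H || nx < 1 || nx > W) next
        q <- ny + (nx - 1L) * H
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# ---- dataset --------------------------------------------------------------

#' Build a synthetic training/evaluation corpus
#'
#' Draws a phantom, a PSF from the bank and a photon level per record, runs
#' the acquisition model and retains the noiseless measurement. All record
#' seeds derive from \code{seed}, so regeneration is bit-identical; use
#' different base seeds for disjoint train/test corpora.
#'
#' @param nPairs number of records.
#' @param psfBank output of [samplePSFBank()].
#' @param phantomMix character vector of phantom kinds to cycle through.
#' @param photonLevels expected photons per unit intensity, sampled per
#'   record (emulates low/medium/high dose acquisitions).
#' @param background scalar background b (intensity units).
#' @param size phantom side in pixels (must match the PSF grid).
#' @param seed integer base seed.
#' @param outDir optional directory: records written as RDS shards plus a
#'   JSON manifest.
#' @return list with \code{records} (each: y0, x, xtilde, psfId, photons,
#'   kind, phantomSeed) and \code{manifest}.
#' @export
buildDataset <- function(nPairs, psfBank, phantomMix = c("bars", "points",
                         "disks", "filaments", "shepp_logan"),
                         photonLevels = c(50, 500, 5000), background = 0,
                         size = 32, seed = 1, outDir = NULL) {
  if (length(psfBank$psfs) == 0L) stop("empty PSF bank")
  set.seed(as.integer(seed))
  psfIds <- sample.int(length(psfBank$psfs), nPairs, replace = TRUE)
  photons <- sample(photonLevels, nPairs, replace = TRUE)
  kinds <- sample(rep_len(phantomMix, nPairs))
  phantomSeeds <- as.integer(seed) * 10000L + seq_len(nPairs)
  records <- vector("list", nPairs)
  for (i in seq_len(nPairs)) {
    ph <- makePhantom(kinds[i], size = size, seed = phantomSeeds[i])
    model <- acquisitionModel(psfBank$psfs[[psfIds[i]]],
                              background = background,
                              photonScale = photons[i])
    pair <- acquire(model, ph$image, rngSeed = phantomSeeds[i] + 1L,
                    modelId = sprintf("psf%d_p%g", psfIds[i], photons[i]))
    records[[i]] <- list(y0 = pair@truth, x = pair@observation,
                         xtilde = pair@noiseless, psfId = psfIds[i],
                         photons = photons[i], kind = kinds[i],
                         phantomSeed = phantomSeeds[i])
  }
  manifest <- list(nPairs = nPairs, seed = seed, size = size,
                   photonLevels = photonLevels, phantomMix = phantomMix,
                   background = background,
                   psfParams = psfBank$params,
                   phantomSeeds = phantomSeeds, psfIds = psfIds,
                   photons = photons, kinds = kinds)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outDir)) stop("unwritable path: ", outDir)
    for (i in seq_len(nPairs))
      saveRDS(records[[i]], file.path(outDir, sprintf("record_%04d.rds", i)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(records = records, manifest = manifest)
}

#' Convert acquisition records to diffusion-range training pairs
#'
#' Intensity images (photon-normalised, roughly [0, 1]) are affinely mapped
#' to the diffusion value convention [-1, 1]. Because the blur kernel has
#' unit sum, the linear measurement model holds unchanged in the mapped
#' coordinates.
#'
#' @param records record list from [buildDataset()].
#' @return list of pairs (y0, x, xtilde) in [-1, 1].
#' @export
toDiffusionPairs <- function(records) {
  lapply(records, function(r)
    list(y0 = toDiffusionRange(r$y0), x = toDiffusionRange(r$x),
         xtilde = toDiffusionRange(r$xtilde), psfId = r$psfId))
}

#' One acquisition model per PSF in a bank
#'
#' Convenience for physics-informed training, where each record's guidance
#' term must use the forward operator of the microscope that produced it.
#'
#' @param psfBank output of [samplePSFBank()].
#' @param ... passed to [acquisitionModel()].
#' @return list of [AcquisitionModel-class], indexable by \code{psfId}.
#' @export
bankModels <- function(psfBank, ...) lapply(psfBank$psfs, acquisitionModel, ...)
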