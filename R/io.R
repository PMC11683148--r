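# Image and checkpoint I/O. 32-bit float TIFF round-trips losslessly;
# PNG is 8/16-bit with values clamped to [0, 1]; CSV is plain text.
# Checkpoints are self-describing RDS bundles (weights + architecture +
# schedule + guidance config).

imageFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tif = , tiff = "tiff", png = "png", csv = "csv",
         stop("unknown extension: ", ext))
}

#' Save an image to TIFF (32-bit float), PNG (8-bit) or CSV
#'
#' TIFF and CSV round-trip losslessly; PNG clamps to [0, 1] and quantises to
#' 8 bits (the maximum abs round-trip error is 1/(2*255)).
#'
#' @param img numeric matrix.
#' @param path output path; the extension selects the format.
#' @return the path, invisibly.
#' @export
saveImage <- function(img, path) {
  fmt <- imageFormat(path)
  if (fmt == "tiff") {
    tiff::writeTIFF(img, path, bits.per.sample = 32L, compression = "none")
  } else if (fmt == "png") {
    png::writePNG(clamp01(img), path)
  } else {
    utils::write.table(img, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Load an image saved by [saveImage()]
#'
#' @param path file path (.tif/.tiff, .png or .csv).
#' @return numeric matrix.
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- imageFormat(path)
  img <- if (fmt == "tiff") {
    v <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(v)) == 3L) v[, , 1] else v
  } else if (fmt == "png") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) v[, , 1] else v
  } else {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  }
  unname(img)
}

#' Write a PSF to TIFF with a JSON sidecar describing the configuration
#'
#' @param psf a [PSFVolume-class].
#' @param config the [OpticalConfig-class] it was built from.
#' @param path .tif output path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @return the path, invisibly.
#' @export
savePSF <- function(psf, config, path) {
  saveImage(psfKernel(psf), path)
  side <- list(mode = psf@mode,
               numericalAperture = config@numericalAperture,
               lambdaEx = config@lambdaEx, lambdaEm = config@lambdaEm,
               pinholeRadius = config@pinholeRadius,
               refractiveIndex = config@refractiveIndex,
               pixelSizeXY = config@pixelSizeXY,
               pixelSizeZ = config@pixelSizeZ,
               gridShape = config@gridShape)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Save a self-describing training checkpoint
#'
#' Bundles the trained denoiser (spec + weights), the diffusion schedule,
#' the guidance configuration and the loss trace, sufficient for
#' restoration without further context.
#'
#' @param path output .rds path.
#' @param denoiser a [Denoiser-class].
#' @param schedule a [DiffusionSchedule-class].
#' @param config a [GuidanceConfig-class].
#' @param losses optional loss trace.
#' @return the path, invisibly.
#' @export
saveCheckpoint <- function(path, denoiser, schedule, config, losses = NULL) {
  saveRDS(list(denoiser = denoiser, schedule = schedule, config = config,
               losses = losses, package = "pidiff", version = "0.99.0"),
          path)
  invisible(path)
}

#' Load a checkpoint written by [saveCheckpoint()]
#' @param path .rds path.
#' @return list with denoiser, schedule, config, losses.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!is.list(ck) || is.null(ck$denoiser)) stop("corrupt checkpoint: ", path)
  ck
}
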