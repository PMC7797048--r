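# TIFF interchange for movies and micrographs. Multifocal movies are stored
# as multi-page 32-bit TIFFs (one tiled frame per page); EM and HCS images
# as single pages. TIFF samples are stored in [0, 1], so physical values
# (photon counts) are divided by a fixed `scale` on write and multiplied
# back on read; the same scale must be used on both sides. The tiff package
# is a suggested dependency: these helpers error informatively if absent.

#' @noRd
.need_tiff <- function() {
  if (!requireNamespace("tiff", quietly = TRUE))
    nm_stop("the 'tiff' package is required for TIFF I/O", "missing_dependency")
}

#' Write a multifocal movie to a multi-page TIFF
#'
#' One page per frame, 32-bit samples. Pixel values (photons) are stored as
#' value / `scale`; read back with the same `scale`. Negative values are
#' clamped to zero. The plane calibration is not embedded; store it
#' alongside with [write_plane_calibration()].
#'
#' @param movie An `mfm_movie` or list of frame matrices.
#' @param path Output file path.
#' @param scale Full-scale photon value mapped to 1.0 (default 2^16).
#' @export
write_mfm_movie <- function(movie, path, scale = 2^16) {
  .need_tiff()
  frames <- if (inherits(movie, "mfm_movie")) movie$frames else movie
  tiff::writeTIFF(lapply(frames, function(f) pmin(pmax(f, 0) / scale, 1)),
                  path, bits.per.sample = 32)
  invisible(path)
}

#' Read a multi-page TIFF as a list of frame matrices
#'
#' @param path TIFF file path.
#' @param scale Full-scale value used at write time.
#' @return List of numeric matrices (one per page), in photons.
#' @export
read_mfm_movie <- function(path, scale = 2^16) {
  .need_tiff()
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    matrix(as.numeric(p) * scale, nrow(p), ncol(p))
  })
}

#' Write a grayscale image (EM micrograph, mask, or one HCS channel) to TIFF
#'
#' @param image Numeric matrix (values scaled by `scale` into \[0, 1\]) or
#'   logical matrix (written as 0/1).
#' @param path Output file path.
#' @param scale Full-scale value mapped to 1.0 (default 1: grey levels are
#'   already fractional).
#' @export
write_image_tiff <- function(image, path, scale = 1) {
  .need_tiff()
  m <- matrix(pmin(pmax(as.numeric(image), 0) / scale, 1),
              nrow(image), ncol(image))
  tiff::writeTIFF(m, path, bits.per.sample = 32)
  invisible(path)
}

#' Read a grayscale TIFF as a numeric matrix
#'
#' Multi-channel pages are reduced to their first channel.
#'
#' @param path TIFF file path.
#' @param scale Full-scale value used at write time.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(path, scale = 1) {
  .need_tiff()
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  matrix(as.numeric(p) * scale, nrow(p), ncol(p))
}
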