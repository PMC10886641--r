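#' Calibrated single-cell fluorescence micrograph
#'
#' A `micrograph` wraps a 2-D intensity matrix together with the spatial
#' calibration (pixels per micron) and the camera bit depth. All downstream
#' morphometric quantities in micrometres derive from `pixels_per_micron`
#' (default 23.4 px/um, the calibration of a 63x super-resolution confocal
#' acquisition).
#'
#' @param pixels numeric matrix of non-negative, finite intensities
#'   (rows = image rows).
#' @param pixels_per_micron spatial calibration, pixels per micron (> 0).
#' @param bit_depth camera bit depth, 8 or 16.
#' @return An object of class `micrograph`: the intensity matrix with
#'   attributes `pixels_per_micron` and `bit_depth`.
#' @examples
#' img <- micrograph(matrix(runif(64, 0, 255), 8, 8))
#' print(img)
#' @export
micrograph <- function(pixels, pixels_per_micron = 23.4, bit_depth = 16) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!all(is.finite(pixels)))
    stop("micrograph intensities must be finite")
  if (any(pixels < 0))
    stop("micrograph intensities must be non-negative")
  if (!is.numeric(pixels_per_micron) || length(pixels_per_micron) != 1 ||
      pixels_per_micron <= 0)
    stop("`pixels_per_micron` must be a single positive number")
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16")
  structure(pixels,
            pixels_per_micron = as.numeric(pixels_per_micron),
            bit_depth = as.integer(bit_depth),
            class = c("micrograph", "matrix", "array"))
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %d-bit, %.3g px/um\n",
              nrow(x), ncol(x), attr(x, "bit_depth"),
              attr(x, "pixels_per_micron")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Binary mitochondrial mask
#'
#' A `binary_mask` is a logical matrix sharing the shape and calibration of
#' the micrograph it was thresholded from.
#'
#' @param pixels logical matrix (TRUE = mitochondria-positive).
#' @param pixels_per_micron spatial calibration inherited from the source
#'   micrograph.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixels_per_micron = 23.4) {
  if (!is.matrix(pixels))
    stop("`pixels` must be a matrix")
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1)))
      stop("`pixels` must be logical or 0/1")
    pixels <- pixels > 0
  }
  if (pixels_per_micron <= 0) stop("`pixels_per_micron` must be > 0")
  structure(pixels,
            pixels_per_micron = as.numeric(pixels_per_micron),
            class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.3g px/um, %d foreground px (%.2f%%)\n",
              nrow(x), ncol(x), attr(x, "pixels_per_micron"),
              sum(x), 100 * mean(x)))
  invisible(x)
}

ppm_of <- function(x) {
  p <- attr(x, "pixels_per_micron")
  if (is.null(p)) stop("object carries no pixels_per_micron calibration")
  p
}

max_intensity <- function(img) {
  bd <- attr(img, "bit_depth")
  if (is.null(bd)) bd <- 16L
  2^bd - 1
}

#' Read a grayscale TIFF micrograph
#'
#' Reads a single-plane grayscale TIFF and attaches the calibration. Values
#' are returned in native integer units (0..255 or 0..65535).
#'
#' @param path path to a TIFF file.
#' @param pixels_per_micron spatial calibration (px/um); the TIFF container
#'   does not carry it.
#' @return A [micrograph].
#' @export
read_micrograph <- function(path, pixels_per_micron = 23.4) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] != 1)
      stop("expected a single-channel grayscale TIFF: ", path)
    px <- px[, , 1]
  }
  bd <- if (max(px) > 255) 16L else
    attr(px, "bits.per.sample") %||% 8L
  storage.mode(px) <- "double"
  micrograph(px, pixels_per_micron = pixels_per_micron,
             bit_depth = if (identical(bd, 16L)) 16L else 8L)
}

#' Write a micrograph as a grayscale TIFF
#'
#' @param img a [micrograph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path) {
  bd <- attr(img, "bit_depth")
  mx <- max_intensity(img)
  m <- pmin(pmax(round(unclass(img)), 0), mx) / mx
  tiff::writeTIFF(m, path, bits.per.sample = bd)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
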