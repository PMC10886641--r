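#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence micrograph by grayscale
#' morphological opening with a disc structuring element and subtracts it.
#' Opening with a disc of the stated radius is the classical rolling-ball
#' background estimate for structures thinner than the ball: any feature that
#' cannot contain the disc is removed from the background and therefore
#' survives the subtraction. Output is clipped at zero; a flat image maps to
#' all zeros.
#'
#' @param img a [micrograph].
#' @param radius_px ball/disc radius in pixels (default 50).
#' @return A background-subtracted [micrograph] of the same shape.
#' @export
subtract_background <- function(img, radius_px = 50) {
  stopifnot(inherits(img, "micrograph"))
  if (radius_px < 1) stop("`radius_px` must be >= 1")
  if (radius_px > min(dim(img)))
    stop(sprintf("rolling-ball radius %d px exceeds the image (%d x %d px)",
                 radius_px, nrow(img), ncol(img)))
  mx <- max_intensity(img)
  x <- unclass(img) / mx
  brush <- EBImage::makeBrush(2 * as.integer(radius_px) + 1, shape = "disc")
  bg <- EBImage::opening(x, brush)
  out <- pmax(x - bg, 0) * mx
  micrograph(out, ppm_of(img), attr(img, "bit_depth"))
}

#' Median filtering
#'
#' Replaces each pixel by the median of its (2r+1)^2 neighbourhood, with
#' reflected edges. Removes the impulse noise of photon-counting detectors
#' without displacing edges.
#'
#' @param img a [micrograph].
#' @param radius_px filter radius r (default 1, i.e. a 3x3 window).
#' @return A filtered [micrograph].
#' @export
denoise_median <- function(img, radius_px = 1) {
  stopifnot(inherits(img, "micrograph"))
  if (radius_px < 1) stop("`radius_px` must be >= 1")
  mx <- max_intensity(img)
  out <- EBImage::medianFilter(unclass(img) / mx, size = as.integer(radius_px)) * mx
  micrograph(out, ppm_of(img), attr(img, "bit_depth"))
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Equalizes the histogram within contextual tiles, limiting the slope of the
#' transfer function (the clip limit) so that noise in flat regions is not
#' over-amplified; tile mappings are bilinearly interpolated. Used to bring
#' dim peripheral mitochondria into the dynamic range before global Otsu
#' thresholding.
#'
#' The image is reflected out to a multiple of the tile size, equalized, and
#' cropped back, so arbitrary image sizes are supported.
#'
#' @param img a [micrograph].
#' @param tile_px side of the contextual tile in pixels (>= 8; default 64).
#' @param clip_limit normalized clip limit in (0, 1] (default 0.01).
#' @return An enhanced [micrograph] spanning the input bit-depth range.
#' @export
enhance_clahe <- function(img, tile_px = 64, clip_limit = 0.01) {
  stopifnot(inherits(img, "micrograph"))
  if (tile_px < 8) stop("`tile_px` must be >= 8")
  if (!(clip_limit > 0 && clip_limit <= 1))
    stop("`clip_limit` must be in (0, 1]")
  mx <- max_intensity(img)
  x <- unclass(img) / mx
  if (diff(range(x)) == 0) return(img)  # nothing to equalize
  h <- nrow(x); w <- ncol(x)
  # >= 2 tiles per axis, and dimensions padded to a tile multiple
  nx <- max(2L, as.integer(round(h / tile_px)))
  ny <- max(2L, as.integer(round(w / tile_px)))
  hp <- ceiling(h / nx) * nx
  wp <- ceiling(w / ny) * ny
  xp <- reflect_pad_to(x, hp, wp)
  # EBImage's limit is in multiples of the mean histogram bin height; the
  # fractional clip limit (fraction of the tile pixel count a bin may hold)
  # converts as clip_limit * bins. Values <= 1 never clip anything.
  lim <- max(clip_limit * 256, 1.01)
  eq <- EBImage::clahe(xp, nx = nx, ny = ny, bins = 256, limit = lim)
  out <- pmin(pmax(eq[seq_len(h), seq_len(w), drop = FALSE], 0), 1) * mx
  micrograph(out, ppm_of(img), attr(img, "bit_depth"))
}

# pad a matrix to (hp, wp) by reflecting its trailing rows/columns
reflect_pad_to <- function(x, hp, wp) {
  h <- nrow(x); w <- ncol(x)
  if (hp > h) {
    extra <- hp - h
    idx <- h - seq_len(extra) + 1L
    idx <- pmax(idx, 1L)
    x <- rbind(x, x[idx, , drop = FALSE])
  }
  if (wp > w) {
    extra <- wp - w
    idx <- w - seq_len(extra) + 1L
    idx <- pmax(idx, 1L)
    x <- cbind(x, x[, idx, drop = FALSE])
  }
  x
}

#' Otsu threshold of an intensity histogram
#'
#' Computes the threshold maximizing the between-class variance of a 256-bin
#' histogram taken over the bit-depth range of the image. Ties resolve to the
#' smallest threshold. Foreground is strictly above the threshold.
#'
#' @param img a [micrograph] with at least two distinct intensities.
#' @return A [binary_mask]; the chosen threshold (in native intensity units)
#'   is attached as attribute `threshold`.
#' @export
binarize_otsu <- function(img) {
  stopifnot(inherits(img, "micrograph"))
  x <- unclass(img)
  if (diff(range(x)) == 0)
    stop("Otsu threshold undefined: image is constant")
  mx <- max_intensity(img)
  # 256 bins over [0, mx]; bin k (1-based) covers ((k-1)*mx/256, k*mx/256]
  bin <- pmin(pmax(ceiling(x / mx * 256), 1L), 256L)
  cnt <- tabulate(bin, nbins = 256L)
  p <- cnt / sum(cnt)
  level <- (seq_len(256) - 0.5) * mx / 256  # bin centres
  w0 <- cumsum(p)
  mu <- cumsum(p * level)
  mu_t <- mu[256]
  # threshold after bin t: classes {1..t}, {t+1..256}
  t_idx <- seq_len(255)
  w0t <- w0[t_idx]; w1t <- 1 - w0t
  num <- (mu_t * w0t - mu[t_idx])^2
  sigma_b <- ifelse(w0t > 0 & w1t > 0, num / (w0t * w1t), -Inf)
  t_best <- which.max(sigma_b)          # smallest argmax
  thr <- t_best * mx / 256              # upper edge of bin t_best
  out <- binary_mask(x > thr, ppm_of(img))
  attr(out, "threshold") <- thr
  out
}

#' Run the fixed preprocessing chain
#'
#' Applies, in this fixed order: rolling-ball background subtraction, median
#' filtering, CLAHE, and Otsu binarization. The order is part of the method
#' definition and is not configurable.
#'
#' @param img a [micrograph].
#' @param rolling_ball_radius_px rolling-ball radius (default 50).
#' @param median_radius_px median filter radius (default 1).
#' @param clahe_tile_px CLAHE tile size (default 64).
#' @param clahe_clip CLAHE clip limit (default 0.01).
#' @return A [binary_mask] of the mitochondria-positive pixels.
#' @export
preprocess_image <- function(img,
                             rolling_ball_radius_px = 50,
                             median_radius_px = 1,
                             clahe_tile_px = 64,
                             clahe_clip = 0.01) {
  img <- subtract_background(img, rolling_ball_radius_px)
  img <- denoise_median(img, median_radius_px)
  img <- enhance_clahe(img, clahe_tile_px, clahe_clip)
  binarize_otsu(img)
}
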