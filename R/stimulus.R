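#' Normalize a stimulus image to fixed mean luminance and RMS contrast
#'
#' Applies the affine pixel transform that gives the visible region of an
#' object image a mean intensity of `target_mean` and a root-mean-square
#' contrast (RMS deviation from the mean, population convention) of
#' `target_rms`. Pixels outside the mask are set to the background gray
#' level 0.5. The defaults (mean 0.5, RMS contrast 0.275) equate luminance
#' and contrast across stimuli so that decoders cannot exploit global
#' intensity differences.
#'
#' @param image numeric matrix of intensities in `[0, 1]`.
#' @param mask logical matrix of the same shape; `TRUE` marks the visible
#'   region. Default: all pixels visible.
#' @param target_mean desired mean intensity over the mask.
#' @param target_rms desired RMS contrast over the mask.
#' @return a numeric matrix of the same shape. If the affine transform pushes
#'   pixels outside `[0, 1]` they are clipped and a warning reports the count
#'   (clipping breaks exactness of the normalization).
#' @export
normalize_stimulus_image <- function(image, mask = NULL, target_mean = 0.5,
                                     target_rms = 0.275) {
  image <- as.matrix(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(image))) stopf("mask and image shapes differ")
  if (!is.logical(mask)) stopf("mask must be logical")
  v <- image[mask]
  if (length(v) < 2L) stopf("mask must select at least 2 pixels")
  m0 <- mean(v)
  rms0 <- sqrt(mean((v - m0)^2))
  if (rms0 == 0 && target_rms > 0)
    stopf("visible region is constant: RMS contrast cannot be normalized")
  a <- if (target_rms == 0) 0 else target_rms / rms0
  b <- target_mean - a * m0
  out <- matrix(0.5, nrow(image), ncol(image))
  out[mask] <- a * v + b
  n_clip <- sum(out[mask] < 0 | out[mask] > 1)
  if (n_clip > 0L) {
    warnf("%d normalized pixel(s) fell outside [0, 1] and were clipped", n_clip)
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  out
}

#' Synthetic object image with a visibility mask
#'
#' Generates a deterministic gray-scale test image: a centered disk (the
#' "object") carrying a smooth two-dimensional sinusoidal pattern on a 0.5
#' gray background. It stands in for the object photographs used in the
#' experiments, which are not redistributable; it is synthetic and carries
#' no object semantics.
#'
#' @param size image side length in pixels.
#' @param radius_frac disk radius as a fraction of `size/2`.
#' @return list with `image` (numeric matrix in `[0, 1]`) and `mask`
#'   (logical matrix, `TRUE` inside the disk).
#' @export
synthetic_object_image <- function(size = 160L, radius_frac = 0.8) {
  cx <- (size + 1) / 2
  x <- matrix(seq_len(size), size, size)
  y <- t(x)
  mask <- (x - cx)^2 + (y - cx)^2 <= (radius_frac * size / 2)^2
  # oblique sinusoid plus a gentle luminance gradient; the peak-to-RMS ratio
  # stays below 0.5 / 0.275, so normalization to the default targets never
  # clips
  img <- 0.5 + 0.3 * sin(2 * pi * (3 * x + 2 * y) / size) +
    0.03 * (x + y) / size
  img <- pmin(pmax(img, 0), 1)
  img[!mask] <- 0.5
  list(image = img, mask = mask)
}
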