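#' Corruption settings for DAE training
#'
#' @param flip_prob Probability in `[0, 1]` that a pixel is corrupted. A
#'   corrupted pixel is *re-drawn* as a fair coin over `{0, 1}` (salt or
#'   pepper), so it keeps its original value half the time and the expected
#'   changed-pixel fraction is `flip_prob / 2`.
#' @param seed Optional integer seed. When `NULL` the current RNG stream is
#'   used, which is how the training loop draws fresh noise every epoch.
#' @return A `corruption_config` object.
#' @export
corruption_config <- function(flip_prob = 0.1, seed = NULL) {
  if (flip_prob < 0 || flip_prob > 1) stop_invalid("`flip_prob` must lie in [0, 1]")
  structure(list(flip_prob = flip_prob, seed = seed), class = "corruption_config")
}

#' Salt-and-pepper corruption of a binary mask
#'
#' Each pixel is independently selected for corruption with probability
#' `flip_prob`, and every selected pixel is replaced by a fair-coin draw over
#' `{0, 1}`. The positions that were selected (re-drawn, whether or not the
#' value changed) are attached as the logical attribute `"corrupted"`.
#'
#' @param y Binary (0/1) matrix.
#' @param cfg A [corruption_config()].
#' @return Corrupted binary matrix of the same shape.
#' @export
#' @examples
#' y <- matrix(0, 8, 8); y[3:6, 3:6] <- 1
#' yt <- corrupt_mask(y, corruption_config(0.2, seed = 1))
corrupt_mask <- function(y, cfg = corruption_config()) {
  if (!is_binary(y)) stop_invalid("`y` must be a binary 0/1 mask")
  run <- function() {
    sel <- matrix(runif(length(y)) < cfg$flip_prob, nrow(y), ncol(y))
    draw <- matrix(as.numeric(runif(length(y)) < 0.5), nrow(y), ncol(y))
    out <- y
    out[sel] <- draw[sel]
    attr(out, "corrupted") <- sel
    out
  }
  if (is.null(cfg$seed)) run() else with_seed(cfg$seed, run())
}

#' Histogram equalization on 256 bins
#'
#' Standard cumulative-histogram equalization: intensities are binned into 256
#' levels and mapped through the empirical CDF. The mapping is monotone
#' non-decreasing, so the rank order of pixel intensities is preserved; a
#' constant image maps to a constant.
#'
#' @param x Grayscale matrix with values in `[0, 1]`.
#' @return Equalized matrix, values in `[0, 1]`.
#' @export
hist_equalize <- function(x) {
  if (any(x < 0) || any(x > 1)) stop_invalid("image values must lie in [0, 1]")
  bins <- pmin(floor(x * 256), 255)          # 0..255
  h <- tabulate(as.vector(bins) + 1L, nbins = 256L)
  cdf <- cumsum(h) / length(x)
  out <- matrix(cdf[bins + 1L], nrow(x), ncol(x))
  out
}

#' Augmentation settings: brightness and contrast jitter
#'
#' @param brightness_range,contrast_range Closed intervals `c(low, high)` of
#'   positive multiplicative factors sampled uniformly per image.
#' @param seed Optional integer seed (`NULL` = current RNG stream).
#' @return An `augment_config` object.
#' @export
augment_config <- function(brightness_range = c(0.8, 1.2),
                           contrast_range = c(0.8, 1.2), seed = NULL) {
  for (r in list(brightness_range, contrast_range)) {
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
      stop_invalid("ranges must be positive intervals c(low, high) with low <= high")
  }
  structure(list(brightness_range = brightness_range,
                 contrast_range = contrast_range, seed = seed),
            class = "augment_config")
}

#' Random brightness/contrast adjustment of an image
#'
#' Samples `b ~ U(brightness_range)` and `c ~ U(contrast_range)`, scales the
#' image by `b`, then scales its deviation from the (post-brightness) mean by
#' `c`, and clips to `[0, 1]`: `clip(c * (b*x - mean(b*x)) + mean(b*x))`.
#' Applied to images only; masks are never augmented.
#'
#' @param x Grayscale matrix in `[0, 1]`.
#' @param cfg An [augment_config()].
#' @return Augmented matrix in `[0, 1]`.
#' @export
augment_brightness_contrast <- function(x, cfg = augment_config()) {
  run <- function() {
    b <- runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
    cc <- runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
    xb <- b * x
    m <- mean(xb)
    clip01(cc * (xb - m) + m)
  }
  if (is.null(cfg$seed)) run() else with_seed(cfg$seed, run())
}
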