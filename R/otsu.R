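# Otsu thresholding on the 8-bit histogram. The threshold separates perfused
# (strictly above threshold) from non-perfused (at or below threshold) pixels.

otsu_from_counts <- function(counts) {
  if (sum(counts > 0L) < 2L)
    stop("degenerate histogram: image has fewer than 2 distinct intensities",
         call. = FALSE)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)             # P(intensity <= t), t = 0..255
  mu    <- cumsum(p * levels)    # first moment up to t
  mu_t  <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # candidates t = 0..254; which.max takes the first maximum, i.e. the
  # smallest qualifying threshold on a plateau
  as.integer(which.max(sigma_b[1:255]) - 1L)
}

#' Otsu threshold of a slab image
#'
#' Returns the intensity `t` in `0..254` maximising the between-class
#' variance of the 256-bin histogram, with the convention that class 0 holds
#' intensities `<= t` and class 1 holds intensities `> t`. Ties on the
#' variance plateau are broken towards the smallest qualifying threshold, so
#' the result is deterministic.
#'
#' @param image a [slab_image()], or an integer matrix/vector of intensities
#'   in `[0, 255]`.
#' @return integer threshold.
#' @export
otsu_threshold <- function(image) {
  px <- if (inherits(image, "slab_image")) image$pixels else image
  px <- as.integer(px)
  if (anyNA(px) || any(px < 0L | px > 255L))
    stop("intensities must be integers in [0, 255]", call. = FALSE)
  otsu_from_counts(tabulate(px + 1L, nbins = 256L))
}
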