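# FFT-based separable 2-D convolution with a per-(shape, kernel) cache of
# kernel transforms. All kernels used in this package are either symmetric or
# appear in antisymmetric pairs, so convolution and correlation coincide for
# every quantity derived from them.

.conv_cache <- new.env(parent = emptyenv())

# kernel transform for circular convolution, centred at the origin; requires
# length(k) <= image extent in each axis
kernel_fft <- function(nr, nc, k_row, k_col, key) {
  if (!is.null(key)) {
    cached <- .conv_cache[[key]]
    if (!is.null(cached)) return(cached)
  }
  hr <- (length(k_row) - 1L) %/% 2L
  hc <- (length(k_col) - 1L) %/% 2L
  if (2L * hr + 1L > nr || 2L * hc + 1L > nc)
    stop("kernel larger than image", call. = FALSE)
  kpad <- matrix(0, nr, nc)
  kpad[((-hr:hr) %% nr) + 1L, ((-hc:hc) %% nc) + 1L] <- outer(k_row, k_col)
  Kf <- stats::fft(kpad)
  if (!is.null(key)) .conv_cache[[key]] <- Kf
  Kf
}

conv2_circular <- function(img, k_row, k_col, key = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  Kf <- kernel_fft(nr, nc, k_row, k_col,
                   if (is.null(key)) NULL else sprintf("%dx%d:%s", nr, nc, key))
  Re(stats::fft(stats::fft(img) * Kf, inverse = TRUE)) / (nr * nc)
}

# replicate-padded convolution: pad edges by at least the kernel half-width
# (rounded up to a 2-3-5-smooth FFT length), convolve circularly, crop back
conv2_replicate <- function(img, k_row, k_col, key = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  hr <- (length(k_row) - 1L) %/% 2L
  hc <- (length(k_col) - 1L) %/% 2L
  nr2 <- stats::nextn(nr + 2L * hr, c(2L, 3L, 5L))
  nc2 <- stats::nextn(nc + 2L * hc, c(2L, 3L, 5L))
  ri <- c(rep(1L, hr), seq_len(nr), rep(nr, nr2 - nr - hr))
  ci <- c(rep(1L, hc), seq_len(nc), rep(nc, nc2 - nc - hc))
  out <- conv2_circular(img[ri, ci, drop = FALSE], k_row, k_col,
                        key = if (is.null(key)) NULL else paste0("pad:", key))
  out[hr + seq_len(nr), hc + seq_len(nc), drop = FALSE]
}
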