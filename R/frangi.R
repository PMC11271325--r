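# Multi-scale Frangi vesselness for 2-D images, used to find and exclude the
# large retinal vessels of the superficial plexus from VAD measurement.
#
# The Hessian is computed by convolution with scale-normalised Gaussian
# derivative kernels (sigma^2 * second derivatives) with replicated borders.

.kernel_cache <- new.env(parent = emptyenv())

gaussian_derivative_kernels <- function(sigma) {
  key <- format(sigma, digits = 12)
  if (!is.null(.kernel_cache[[key]])) return(.kernel_cache[[key]])
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-h):h
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- list(
    g  = g,
    g1 = -x / sigma^2 * g,
    g2 = (x^2 - sigma^2) / sigma^4 * g
  )
  .kernel_cache[[key]] <- k
  k
}


#' Multi-scale Frangi vesselness
#'
#' Classic Hessian-eigenvalue vesselness for bright tubular structures on a
#' dark background, evaluated at each scale in `sigmas` (scale-normalised
#' second derivatives) and combined by the pixel-wise maximum. At each scale
#' the response is
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`
#' where `Rb` is the eigenvalue ratio (blobness) and `S` the Frobenius norm
#' of the Hessian (structureness); pixels whose principal curvature is
#' non-negative (dark or flat) score 0. The structureness scale `c` is
#' anchored to the image's dynamic range (`c = range/4`) rather than to the
#' maximum Hessian norm of the particular image: a genuine bright ridge at a
#' matching scale reaches `S` of roughly 0.4x its contrast while white noise
#' stays below about 0.15x the full range, so this choice keeps the response
#' comparable across images and leaves structure-free images with a
#' uniformly weak response.
#'
#' @param image a [slab_image()] or numeric matrix.
#' @param sigmas Gaussian scales in pixels; the default targets large vessels
#'   only.
#' @param beta blobness sensitivity (0.5 is the standard choice).
#' @return numeric matrix of vesselness values in `[0, 1)`.
#' @export
frangi_vesselness <- function(image, sigmas = c(4, 6, 8, 10), beta = 0.5) {
  px <- if (inherits(image, "slab_image")) image$pixels else image
  img <- matrix(as.numeric(px), nrow(px), ncol(px))
  V <- matrix(0, nrow(img), ncol(img))
  c2 <- (diff(range(img)) / 4)^2
  if (c2 <= 0) return(V)
  for (s in sigmas) {
    k <- gaussian_derivative_kernels(s)
    Irr <- s^2 * conv2_replicate(img, k$g2, k$g, key = sprintf("g2g:%g", s))
    Icc <- s^2 * conv2_replicate(img, k$g, k$g2, key = sprintf("gg2:%g", s))
    Irc <- s^2 * conv2_replicate(img, k$g1, k$g1, key = sprintf("g1g1:%g", s))
    half_tr <- (Irr + Icc) / 2
    root <- sqrt(((Irr - Icc) / 2)^2 + Irc^2)
    l1 <- half_tr + root
    l2 <- half_tr - root
    swap <- abs(l1) > abs(l2)
    lam_lo <- ifelse(swap, l2, l1)   # smaller magnitude
    lam_hi <- ifelse(swap, l1, l2)   # larger magnitude (sign carries)
    S2 <- l1^2 + l2^2
    Rb2 <- (lam_lo / lam_hi)^2
    Rb2[lam_hi == 0] <- 0
    v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    v[lam_hi >= 0] <- 0              # bright ridge requires negative curvature
    v[!is.finite(v)] <- 0
    V <- pmax(V, v)
  }
  V
}

#' Large-vessel exclusion mask for the SVP
#'
#' Thresholds the multi-scale Frangi response restricted to large scales.
#' The cutoff policy is Otsu on the non-zero vesselness response (quantised
#' to 256 bins), combined with an isotropy floor: blob-like/isotropic
#' structures are bounded by `exp(-1/(2 beta^2))` (about 0.135 for
#' `beta = 0.5`), so responses below `floor` are never accepted. The mask is
#' empty when the image has no large-scale tubular structure.
#'
#' @param svp the SVP [slab_image()] (or a numeric matrix).
#' @param sigmas large-vessel scales in pixels.
#' @param vesselness_floor minimum accepted vesselness.
#' @inheritParams frangi_vesselness
#' @return logical matrix marking large-vessel pixels.
#' @export
large_vessel_mask <- function(svp, sigmas = c(4, 6, 8, 10),
                              vesselness_floor = 0.2, beta = 0.5) {
  if (inherits(svp, "slab_image") && svp$layer != "SVP")
    stop("large-vessel exclusion is defined for the SVP slab", call. = FALSE)
  V <- frangi_vesselness(svp, sigmas = sigmas, beta = beta)
  nz <- V[V > 0]
  if (length(nz) < 2L || max(nz) == min(nz))
    return(V >= vesselness_floor & V > 0)
  q <- matrix(as.integer(floor(V / max(nz) * 255)), nrow(V), ncol(V))
  counts <- tabulate(q[V > 0] + 1L, nbins = 256L)
  thr <- if (sum(counts > 0L) < 2L) 0L else otsu_from_counts(counts)
  (V > 0) & (q > thr) & (V >= vesselness_floor)
}
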