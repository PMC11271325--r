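# Shared fixtures and independent oracles, all built in code.

# solid axis-aligned rectangle mask
rect_mask <- function(shape, rows, cols) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[rows, cols] <- TRUE
  m
}

# rasterised disk (pixel centres within radius)
disk_at <- function(shape, center, radius) {
  d <- sqrt(outer((seq_len(shape[1]) - center[1])^2,
                  (seq_len(shape[2]) - center[2])^2, "+"))
  d <= radius
}

# independent Otsu oracle: exhaustive scan of all 255 candidate thresholds,
# scoring between-class variance from raw class means
otsu_brute <- function(px) {
  px <- as.integer(px)
  n <- length(px)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:254) {
    lo <- px[px <= t]; hi <- px[px > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / n
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best * (1 + 1e-12) && v > best) { best <- v; best_t <- t }
  }
  best_t
}

# independent ATC oracle: per-pixel inverse affine mapping, double loop
atc_brute <- function(amn, faz = NULL, scale = 2) {
  idx <- which(amn, arr.ind = TRUE)
  ctr <- c(mean(idx[, 1]), mean(idx[, 2]))
  nr <- nrow(amn); nc <- ncol(amn)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    sr <- floor(ctr[1] + (r - ctr[1]) / scale + 0.5)
    sc <- floor(ctr[2] + (cc - ctr[2]) / scale + 0.5)
    if (sr >= 1 && sr <= nr && sc >= 1 && sc <= nc && amn[sr, sc])
      out[r, cc] <- TRUE
  }
  out <- out & !amn
  if (!is.null(faz)) out <- out & !faz
  out
}

# independent ring-segment oracle: brute-force distance check per pixel
rs_brute <- function(amn, center) {
  nr <- nrow(amn); nc <- ncol(amn)
  d_amn <- apply(which(amn, arr.ind = TRUE), 1, function(p)
    sqrt((p[1] - center[1])^2 + (p[2] - center[2])^2))
  r_min <- min(d_amn); r_max <- max(d_amn)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    d <- sqrt((r - center[1])^2 + (cc - center[2])^2)
    out[r, cc] <- d >= r_min && d <= r_max && !amn[r, cc]
  }
  out
}

# closed-form Dice of two equal circles of radius r at centre offset d
circle_dice <- function(d, r) {
  if (d >= 2 * r) return(0)
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  lens / (pi * r^2)
}

# a random irregular (non-convex) lesion: union of a few overlapping ellipses
random_blob_mask <- function(shape, center, max_r) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in 1:3) {
    ctr <- center + stats::runif(2, -max_r / 3, max_r / 3)
    ax <- stats::runif(2, max_r / 3, max_r)
    ang <- stats::runif(1, 0, pi)
    dr <- matrix(seq_len(shape[1]) - ctr[1], shape[1], shape[2])
    dc <- matrix(seq_len(shape[2]) - ctr[2], shape[1], shape[2], byrow = TRUE)
    u <- cos(ang) * dr + sin(ang) * dc
    v <- -sin(ang) * dr + cos(ang) * dc
    m <- m | ((u / ax[1])^2 + (v / ax[2])^2 <= 1)
  }
  m
}

# minimal valid VAD record table for cohort statistics tests
fake_vad_records <- function(vads) {
  # vads: named list eye -> named list layer -> c(AMN, ATC, RS)
  rows <- list()
  for (eye in names(vads)) for (layer in names(vads[[eye]])) {
    v <- vads[[eye]][[layer]]
    rows[[length(rows) + 1L]] <- data.frame(
      eye_id = eye, layer = layer, region = c("AMN", "ATC", "RS"),
      vad = v, threshold = 100L, n_pixels = 100L, n_excluded = 0L,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# uniform fully-crossed cohort where every layer gets the same three VADs
uniform_vad_cohort <- function(eyes, amn, atc, rs) {
  vads <- lapply(eyes, function(e)
    stats::setNames(rep(list(c(amn[e], atc[e], rs[e])), 5),
                    c("SVP", "ICP", "DCP", "CC", "CHOROID")))
  names(vads) <- eyes
  fake_vad_records(vads)
}
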