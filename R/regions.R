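# Intra-eye comparator regions derived from the AMN and FAZ segmentations:
# the adjacent tissue control (ATC) and the fovea-centred ring segment (RS).
#
# Geometry conventions: masks are logical matrices; a pixel's centre sits at
# its integer (row, col) index; all distances and centroids are computed on
# pixel centres. Regions are clipped silently to the image frame.

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  c(row = mean(idx[, 1L]), col = mean(idx[, 2L]))
}

#' Fovea centre from the FAZ segmentation
#'
#' The ring segment is centred on the fovea; with only the FAZ segmentation
#' available, the fovea centre is taken as the centroid (mean pixel-centre
#' coordinate) of the FAZ mask.
#'
#' @param faz_mask logical matrix marking the foveal avascular zone.
#' @return numeric `(row, col)` of the FAZ centroid.
#' @export
fovea_center <- function(faz_mask) {
  if (!any(faz_mask))
    stop("no fovea reference: FAZ mask is empty", call. = FALSE)
  mask_centroid(faz_mask)
}

#' Build the adjacent tissue control (ATC)
#'
#' The lesion footprint is scaled by a linear factor about its centroid
#' ("doubled in size with the same midpoint"), the lesion itself is excluded,
#' and any part of the band falling inside the FAZ is excluded too, leaving
#' the tissue directly adjacent to the lesion.
#'
#' Rasterisation is by inverse mapping: each image pixel centre `p` is mapped
#' to `c + (p - c)/scale` (with `c` the lesion centroid) and looked up in the
#' lesion mask by nearest neighbour (half-up rounding), so the scaled
#' footprint is exactly the preimage of the lesion under the affine scaling.
#'
#' @param amn_mask logical lesion mask (non-empty).
#' @param faz_mask optional logical FAZ mask to exclude.
#' @param scale linear scale factor `> 1`; the default 2 doubles the lesion's
#'   linear size (4x area for a solid shape). Use `sqrt(2)` for area doubling.
#' @return logical ATC mask.
#' @export
build_atc <- function(amn_mask, faz_mask = NULL, scale = 2) {
  if (!any(amn_mask)) stop("lesion mask is empty", call. = FALSE)
  if (!is.numeric(scale) || scale <= 1)
    stop("`scale` must be > 1", call. = FALSE)
  nr <- nrow(amn_mask); nc <- ncol(amn_mask)
  ctr <- mask_centroid(amn_mask)
  # the affine scaling is separable, so precompute per-axis nearest-neighbour
  # lookup vectors
  map_r <- round_half_up(ctr[["row"]] + (seq_len(nr) - ctr[["row"]]) / scale)
  map_c <- round_half_up(ctr[["col"]] + (seq_len(nc) - ctr[["col"]]) / scale)
  ok_r <- map_r >= 1 & map_r <= nr
  ok_c <- map_c >= 1 & map_c <= nc
  scaled <- matrix(FALSE, nr, nc)
  scaled[ok_r, ok_c] <- amn_mask[map_r[ok_r], map_c[ok_c]]
  # forward extent check: report when the scaled footprint ran off the frame
  idx <- which(amn_mask, arr.ind = TRUE)
  fr <- ctr[["row"]] + (range(idx[, 1L]) - ctr[["row"]]) * scale
  fc <- ctr[["col"]] + (range(idx[, 2L]) - ctr[["col"]]) * scale
  if (fr[1] < 0.5 || fr[2] > nr + 0.5 || fc[1] < 0.5 || fc[2] > nc + 0.5)
    message("ATC: scaled lesion footprint clipped at the image border")
  atc <- scaled & !amn_mask
  if (!is.null(faz_mask)) atc <- atc & !faz_mask
  if (!any(atc)) {
    faz_overlap <- if (is.null(faz_mask)) 0L else sum(scaled & faz_mask)
    stop(sprintf(paste0("degenerate ATC: empty after exclusions ",
                        "(lesion %d px, scaled footprint %d px, ",
                        "FAZ overlap %d px)"),
                 sum(amn_mask), sum(scaled), faz_overlap), call. = FALSE)
  }
  atc
}

# Euclidean distance of every pixel centre from `center`
distance_map <- function(nr, nc, center) {
  sqrt(outer((seq_len(nr) - center[[1L]])^2,
             (seq_len(nc) - center[[2L]])^2, "+"))
}

#' Build the ring segment (RS)
#'
#' The closed annulus around `center` whose inner and outer circles are
#' tangent to the lesion (radii equal to the minimum and maximum pixel-centre
#' distance from the centre to the lesion), with the lesion excluded. The
#' rationale is that tissue at equal distance from the fovea has comparable
#' vascular density.
#'
#' @param amn_mask logical lesion mask (non-empty).
#' @param center `(row, col)` annulus centre, typically [fovea_center()].
#' @return logical RS mask.
#' @export
build_ring_segment <- function(amn_mask, center) {
  if (!any(amn_mask)) stop("lesion mask is empty", call. = FALSE)
  if (length(center) != 2L || any(!is.finite(unlist(center))))
    stop("`center` must be a finite (row, col) pair", call. = FALSE)
  nr <- nrow(amn_mask); nc <- ncol(amn_mask)
  d <- distance_map(nr, nc, center)
  d_amn <- d[amn_mask]
  r_min <- min(d_amn); r_max <- max(d_amn)
  if (r_min == r_max)
    warning("ring segment degenerates: lesion pixels all at one radius",
            call. = FALSE)
  rs <- d >= r_min & d <= r_max & !amn_mask
  if (!any(rs))
    stop("degenerate RS: annulus contains no pixels outside the lesion",
         call. = FALSE)
  rs
}

#' Construct all comparator regions for one eye
#'
#' Bundles the lesion (AMN) and FAZ masks with the derived adjacent tissue
#' control and ring segment. The RS is not FAZ-excluded (only the ATC rule
#' removes FAZ pixels); any RS/FAZ overlap is reported as a diagnostic.
#'
#' @param labels a [label_mask()], or a logical AMN mask.
#' @param faz_mask logical FAZ mask (ignored when `labels` is a
#'   [label_mask()]).
#' @param atc_scale linear scale factor for [build_atc()].
#' @return object of class `region_set` with fields `amn`, `faz`, `atc`,
#'   `rs`, `fovea_center`, `atc_scale`, and `rs_faz_overlap_px`.
#' @export
region_set <- function(labels, faz_mask = NULL, atc_scale = 2) {
  if (inherits(labels, "label_mask")) {
    amn <- mask_of(labels, "AMN")
    faz <- mask_of(labels, "FAZ")
  } else {
    amn <- labels
    faz <- faz_mask
    if (is.null(faz)) stop("`faz_mask` is required", call. = FALSE)
  }
  if (!any(amn))
    stop("empty lesion: no AMN pixels in the label map", call. = FALSE)
  if (any(amn & faz))
    warning("AMN lesion overlaps the FAZ; expected to lie outside",
            call. = FALSE)
  ctr <- fovea_center(faz)
  structure(
    list(amn = amn, faz = faz,
         atc = build_atc(amn, faz, scale = atc_scale),
         rs = build_ring_segment(amn, ctr),
         fovea_center = ctr, atc_scale = atc_scale,
         rs_faz_overlap_px = NA_integer_),
    class = "region_set"
  ) -> rs
  rs$rs_faz_overlap_px <- sum(rs$rs & rs$faz)
  rs
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf(paste0("<region_set> AMN %d px  ATC %d px (scale %.3g)  ",
                     "RS %d px  FAZ %d px  fovea (%.1f, %.1f)\n"),
              sum(x$amn), sum(x$atc), x$atc_scale, sum(x$rs), sum(x$faz),
              x$fovea_center[["row"]], x$fovea_center[["col"]]))
  if (x$rs_faz_overlap_px > 0)
    cat(sprintf("  note: RS overlaps FAZ by %d px\n", x$rs_faz_overlap_px))
  invisible(x)
}

#' Export a region set as a multi-label NIfTI for visual QC
#'
#' Labels: 0 background, 1 AMN, 2 FAZ, 3 ATC, 4 RS (earlier labels take
#' priority where regions overlap).
#'
#' @param regions a [region_set()].
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
regions_to_nifti <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  lab <- matrix(0L, nrow(regions$amn), ncol(regions$amn))
  lab[regions$rs]  <- 4L
  lab[regions$atc] <- 3L
  lab[regions$faz] <- 2L
  lab[regions$amn] <- 1L
  to_nifti(lab, path)
}
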