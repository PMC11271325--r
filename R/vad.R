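# Vessel area density (VAD): fraction of above-threshold ("perfused") pixels
# within a region, per slab and comparator region.

#' Quantification configuration
#'
#' Bundles the tunable parameters of [quantify_eye()].
#'
#' @param svp_sigmas Frangi scales (px) for SVP large-vessel exclusion.
#' @param svp_exclusion apply large-vessel exclusion to the SVP slab.
#' @param per_region_threshold compute one Otsu threshold per region instead
#'   of one per slab. The slab-global threshold is the default: a per-region
#'   threshold would adapt to a lesion-localised deficit and bias the
#'   lesion-vs-control comparison towards the null. The per-region mode
#'   exists for sensitivity analysis only.
#' @param vesselness_floor,frangi_beta passed to [large_vessel_mask()].
#' @return a named list of class `quantify_config`.
#' @export
quantify_config <- function(svp_sigmas = c(4, 6, 8, 10),
                            svp_exclusion = TRUE,
                            per_region_threshold = FALSE,
                            vesselness_floor = 0.2,
                            frangi_beta = 0.5) {
  structure(list(svp_sigmas = svp_sigmas, svp_exclusion = svp_exclusion,
                 per_region_threshold = per_region_threshold,
                 vesselness_floor = vesselness_floor,
                 frangi_beta = frangi_beta),
            class = "quantify_config")
}

#' Vessel area density of one region
#'
#' Evaluated pixels are the region minus the exclusion mask; the VAD is the
#' fraction of evaluated pixels with intensity strictly above the threshold
#' (equality counts as non-perfused). Excluded pixels are removed from both
#' numerator and denominator.
#'
#' @param slab a [slab_image()].
#' @param region_mask logical region mask.
#' @param threshold intensity threshold (see [otsu_threshold()]).
#' @param exclusion_mask optional logical mask of pixels to remove from the
#'   evaluation (e.g. large vessels).
#' @param region region label stored in the record (`"AMN"`, `"ATC"`, `"RS"`).
#' @return one-row data frame (a VAD record) with columns `eye_id`, `layer`,
#'   `region`, `vad`, `threshold`, `n_pixels`, `n_excluded`.
#' @export
compute_vad <- function(slab, region_mask, threshold, exclusion_mask = NULL,
                        region = NA_character_) {
  stopifnot(inherits(slab, "slab_image"))
  if (!identical(dim(region_mask), dim(slab$pixels)))
    stop("region mask and slab dimensions differ", call. = FALSE)
  eval_mask <- region_mask
  n_excluded <- 0L
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(slab$pixels)))
      stop("exclusion mask and slab dimensions differ", call. = FALSE)
    n_excluded <- sum(region_mask & exclusion_mask)
    eval_mask <- region_mask & !exclusion_mask
  }
  n <- sum(eval_mask)
  if (n == 0L)
    stop(sprintf("empty evaluation region%s",
                 if (is.na(region)) "" else sprintf(" '%s'", region)),
         call. = FALSE)
  above <- sum(slab$pixels[eval_mask] > threshold)
  data.frame(eye_id = slab$eye_id, layer = slab$layer, region = region,
             vad = above / n, threshold = as.integer(threshold),
             n_pixels = n, n_excluded = n_excluded,
             stringsAsFactors = FALSE)
}

#' Quantify all slabs of one eye
#'
#' For each of the five vascular slabs, one Otsu threshold is computed on the
#' full slab and applied to the AMN, ATC and RS regions. The Frangi
#' large-vessel exclusion is applied to the SVP only; the choriocapillaris
#' and choroid (and the other retinal plexuses) are thresholded without it.
#'
#' @param slabs named list of [slab_image()]s containing at least
#'   `SVP`, `ICP`, `DCP`, `CC`, `CHOROID`.
#' @param regions a [region_set()] co-registered with the slabs.
#' @param config a [quantify_config()].
#' @return data frame of 15 VAD records (5 slabs x 3 regions) of class
#'   `vad_records`.
#' @export
quantify_eye <- function(slabs, regions, config = quantify_config()) {
  stopifnot(inherits(regions, "region_set"))
  missing_layers <- setdiff(VASCULAR_LAYERS, names(slabs))
  if (length(missing_layers))
    stop(sprintf("missing slab(s): %s", paste(missing_layers, collapse = ", ")),
         call. = FALSE)
  for (layer in VASCULAR_LAYERS)
    if (!identical(dim(slabs[[layer]]$pixels), dim(regions$amn)))
      stop(sprintf("co-registration error: %s slab dimensions differ from the regions",
                   layer), call. = FALSE)
  svp_excl <- if (isTRUE(config$svp_exclusion))
    large_vessel_mask(slabs$SVP, sigmas = config$svp_sigmas,
                      vesselness_floor = config$vesselness_floor,
                      beta = config$frangi_beta)
  else NULL
  region_masks <- list(AMN = regions$amn, ATC = regions$atc, RS = regions$rs)
  rows <- vector("list", length(VASCULAR_LAYERS) * length(region_masks))
  i <- 0L
  for (layer in VASCULAR_LAYERS) {
    slab <- slabs[[layer]]
    excl <- if (layer == "SVP") svp_excl else NULL
    thr <- if (!config$per_region_threshold) otsu_threshold(slab) else NULL
    for (region in names(region_masks)) {
      rthr <- if (config$per_region_threshold)
        otsu_threshold(slab$pixels[region_masks[[region]]])
      else thr
      i <- i + 1L
      rows[[i]] <- compute_vad(slab, region_masks[[region]], rthr,
                               exclusion_mask = excl, region = region)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("vad_records", class(out))
  out
}
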