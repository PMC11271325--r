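# Seeded synthetic OCTA phantoms: per-slab perfusion textures with an
# avascular FAZ, a parafoveal lesion with optional layer-specific perfusion
# deficit, bright large-vessel arcs in the SVP, an IR reflectance image, and
# en-face EZ/OPL lesion footprints with radial (Henle-fibre-like)
# displacement. Everything is deterministic given the seed.
#
# Perfusion textures are thresholded band-pass (Gaussian-smoothed) noise, not
# grown vessel trees: the smoothed field is normalised to an exactly standard
# normal marginal, so a pixel is perfused with probability exactly equal to
# the configured fraction while neighbouring pixels stay spatially
# correlated at the configured texture scale.

DEFAULT_LAYER_PARAMS <- list(
  SVP     = list(base_vessel_fraction = 0.38, texture_scale_px = 3.0),
  ICP     = list(base_vessel_fraction = 0.32, texture_scale_px = 2.5),
  DCP     = list(base_vessel_fraction = 0.34, texture_scale_px = 2.5),
  CC      = list(base_vessel_fraction = 0.42, texture_scale_px = 1.5),
  CHOROID = list(base_vessel_fraction = 0.39, texture_scale_px = 6.0)
)

#' Configuration of a synthetic eye
#'
#' Geometry defaults scale with the frame so that desk-scale phantoms keep
#' the proportions of a fovea-centred 512 x 512 scan: FAZ radius
#' `0.09 min(shape)`, lesion eccentricity `0.22 min(shape)`, lesion
#' semi-axes `(0.07, 0.055) min(shape)`.
#'
#' @param seed integer RNG seed; the whole phantom is a pure function of the
#'   configuration including this seed.
#' @param shape `(rows, cols)` of the frame.
#' @param eye_id identifier attached to all generated images.
#' @param fovea_center `(row, col)`; default frame centre.
#' @param faz_radius_px radius of the avascular foveal disk.
#' @param lesion list with `shape` (`"ellipse"` or `"blob"`), `axes`
#'   (semi-axes, px), `angle` (ellipse orientation, rad), `eccentricity_px`
#'   (distance of lesion centre from the fovea), `angle_pos` (position angle
#'   of the lesion centre around the fovea, rad), `irregularity` (radial
#'   boundary perturbation for blobs, fraction), `center` (overrides
#'   eccentricity/angle_pos when given). The lesion must lie outside the FAZ.
#' @param layer_params named per-slab list of `base_vessel_fraction` (the
#'   probability a pixel is perfused) and `texture_scale_px` (Gaussian
#'   correlation scale of the texture).
#' @param lesion_deficit named per-slab fractions in `[0, 1]`; the perfusion
#'   probability inside the lesion is multiplied by `1 - deficit`.
#' @param svp_large_vessels list with `count`, `width_px`, `intensity`.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param speckle if `TRUE`, noise is multiplicative (log-normal speckle)
#'   instead of additive.
#' @param vessel_intensity,background_intensity intensity levels of perfused
#'   and non-perfused tissue before noise.
#' @param opl_displacement_px,ez_displacement_px radial displacement of the
#'   OPL and EZ en-face lesion footprints (px); by default the EZ footprint
#'   coincides with the IR footprint.
#' @param displacement_direction `"radial"` (along the ray from the fovea
#'   through the lesion centroid) or `"nasal"` (fixed horizontal).
#' @return a named list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             shape = c(512L, 512L),
                             eye_id = "eye01",
                             fovea_center = NULL,
                             faz_radius_px = NULL,
                             lesion = list(),
                             layer_params = NULL,
                             lesion_deficit = NULL,
                             svp_large_vessels = NULL,
                             noise_sd = 18,
                             speckle = FALSE,
                             vessel_intensity = 200,
                             background_intensity = 30,
                             opl_displacement_px = NULL,
                             ez_displacement_px = 0,
                             displacement_direction = c("radial", "nasal")) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 32L))
  base <- min(shape)
  if (is.null(fovea_center)) fovea_center <- (shape + 1) / 2
  if (is.null(faz_radius_px)) faz_radius_px <- 0.09 * base
  les <- utils::modifyList(
    list(shape = "ellipse", axes = c(0.07, 0.055) * base, angle = pi / 6,
         eccentricity_px = 0.22 * base, angle_pos = pi / 4,
         irregularity = 0, center = NULL),
    lesion)
  if (is.null(les$center))
    les$center <- fovea_center + les$eccentricity_px *
      c(cos(les$angle_pos), sin(les$angle_pos))
  lp <- DEFAULT_LAYER_PARAMS
  if (!is.null(layer_params))
    for (nm in names(layer_params))
      lp[[nm]] <- utils::modifyList(lp[[nm]], layer_params[[nm]])
  fractions <- vapply(lp, `[[`, numeric(1), "base_vessel_fraction")
  if (any(fractions <= 0 | fractions >= 1))
    stop("base_vessel_fraction must lie in (0, 1)", call. = FALSE)
  deficit <- c(SVP = 0, ICP = 0, DCP = 0, CC = 0, CHOROID = 0)
  if (!is.null(lesion_deficit)) {
    bad <- setdiff(names(lesion_deficit), names(deficit))
    if (length(bad)) stop("unknown layer in lesion_deficit: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    deficit[names(lesion_deficit)] <- lesion_deficit
  }
  if (any(deficit < 0 | deficit > 1))
    stop("lesion deficit fractions must lie in [0, 1]", call. = FALSE)
  lv <- utils::modifyList(
    list(count = 3L, width_px = max(4L, round(10 * base / 512)),
         intensity = 240),
    svp_large_vessels %||% list())
  if (is.null(opl_displacement_px)) opl_displacement_px <- round(0.03 * base)
  structure(
    list(seed = as.integer(seed), shape = shape, eye_id = eye_id,
         fovea_center = fovea_center, faz_radius_px = faz_radius_px,
         lesion = les, layer_params = lp, lesion_deficit = deficit,
         svp_large_vessels = lv, noise_sd = noise_sd, speckle = speckle,
         vessel_intensity = vessel_intensity,
         background_intensity = background_intensity,
         opl_displacement_px = opl_displacement_px,
         ez_displacement_px = ez_displacement_px,
         displacement_direction = match.arg(displacement_direction)),
    class = "synthetic_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- geometric primitives --------------------------------------------------

disk_mask <- function(shape, center, radius) {
  distance_map(shape[1L], shape[2L], center) <= radius
}

# ellipse (or radially perturbed blob) membership tested at pixel centres
lesion_footprint <- function(shape, les, harmonics = NULL) {
  nr <- shape[1L]; nc <- shape[2L]
  dr <- matrix(seq_len(nr) - les$center[1L], nr, nc)
  dc <- matrix(seq_len(nc) - les$center[2L], nr, nc, byrow = TRUE)
  u <- cos(les$angle) * dr + sin(les$angle) * dc
  v <- -sin(les$angle) * dr + cos(les$angle) * dc
  rho <- sqrt((u / les$axes[1L])^2 + (v / les$axes[2L])^2)
  bound <- 1
  if (!is.null(harmonics) && les$irregularity > 0) {
    phi <- atan2(v, u)
    mod <- 0
    for (k in seq_along(harmonics$a))
      mod <- mod + (harmonics$a[k] * cos((k + 1) * phi) +
                    harmonics$b[k] * sin((k + 1) * phi)) / (k + 1)
    bound <- pmax(0.3, 1 + les$irregularity * mod)
  }
  rho <= bound
}

# unit-variance stationary Gaussian random field with Gaussian autocovariance
smooth_field <- function(shape, scale_px) {
  w <- matrix(stats::rnorm(prod(shape)), shape[1L], shape[2L])
  if (scale_px <= 0) return(w)
  h <- max(1L, as.integer(ceiling(3 * scale_px)))
  x <- (-h):h
  g <- exp(-x^2 / (2 * scale_px^2))
  g <- g / sum(g)
  # circular boundary keeps the field stationary, so after normalisation the
  # marginal is exactly standard normal at every pixel
  f <- conv2_circular(w, g, g, key = sprintf("smooth:%g", scale_px))
  f / sum(g^2)  # sd of the separable kernel: sqrt(sum(outer(g, g)^2))
}

# smooth quadratic (Bezier) arcs crossing the frame; returns the dilated tube
# mask and the rasterised centre lines
draw_large_vessels <- function(shape, count, width_px) {
  nr <- shape[1L]; nc <- shape[2L]
  center_line <- matrix(FALSE, nr, nc)
  if (count < 1L) return(list(mask = center_line, center_line = center_line))
  perimeter_point <- function(t) {
    # t in [0, 1) runs around the frame border
    p <- t * 2 * (nr + nc)
    if (p < nc) c(1, 1 + p)
    else if (p < nc + nr) c(1 + (p - nc), nc)
    else if (p < 2 * nc + nr) c(nr, nc - (p - nc - nr))
    else c(nr - (p - 2 * nc - nr), 1)
  }
  n_samp <- 3L * (nr + nc)
  tt <- seq(0, 1, length.out = n_samp)
  for (i in seq_len(count)) {
    t1 <- stats::runif(1)
    t2 <- (t1 + 0.5 + stats::runif(1, -0.1, 0.1)) %% 1
    a <- perimeter_point(t1); b <- perimeter_point(t2)
    mid <- (a + b) / 2
    ctrl <- mid + stats::runif(2, -0.25, 0.25) * c(nr, nc)
    pr <- (1 - tt)^2 * a[1] + 2 * (1 - tt) * tt * ctrl[1] + tt^2 * b[1]
    pc <- (1 - tt)^2 * a[2] + 2 * (1 - tt) * tt * ctrl[2] + tt^2 * b[2]
    ri <- pmin(pmax(round_half_up(pr), 1), nr)
    ci <- pmin(pmax(round_half_up(pc), 1), nc)
    center_line[cbind(ri, ci)] <- TRUE
  }
  brush_size <- 2L * (as.integer(width_px) %/% 2L) + 1L
  mask <- if (brush_size >= 3L)
    EBImage::dilate(center_line * 1, EBImage::makeBrush(brush_size, "disc")) > 0.5
  else center_line
  list(mask = mask, center_line = center_line)
}

clip_to_8bit <- function(img) {
  matrix(as.integer(round_half_up(pmin(pmax(img, 0), 255))),
         nrow(img), ncol(img))
}

# ---- generators ------------------------------------------------------------

#' Generate one synthetic eye
#'
#' Produces the five vascular slabs plus the IR image, the AMN/FAZ label
#' mask, the comparator regions, the ground-truth large-vessel mask, and a
#' ground-truth table of true perfused fractions per slab and region
#' (measured on the pre-noise binary textures).
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_eye`: list with `slabs`, `label_mask`,
#'   `regions`, `ground_truth`, `large_vessel_truth`, `config`.
#' @export
generate_eye <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_eye_impl(config))
}

generate_eye_impl <- function(config) {
  shape <- config$shape
  harmonics <- NULL
  if (config$lesion$shape == "blob")
    harmonics <- list(a = stats::rnorm(4), b = stats::rnorm(4))
  lesion <- lesion_footprint(shape, config$lesion, harmonics)
  faz <- disk_mask(shape, config$fovea_center, config$faz_radius_px)
  if (!any(lesion))
    stop("invalid synthetic config: lesion footprint is empty", call. = FALSE)
  if (any(lesion & faz))
    stop("invalid synthetic config: lesion overlaps the FAZ", call. = FALSE)
  labels <- matrix(0L, shape[1L], shape[2L])
  labels[faz] <- 2L
  labels[lesion] <- 1L
  lm <- label_mask(labels)
  regions <- region_set(lm, atc_scale = 2)
  region_masks <- list(AMN = regions$amn, ATC = regions$atc, RS = regions$rs)

  vessels <- draw_large_vessels(shape, config$svp_large_vessels$count,
                                config$svp_large_vessels$width_px)
  slabs <- list()
  gt_frac <- numeric(0); gt_layer <- character(0); gt_region <- character(0)
  gt_base <- numeric(0); gt_deficit <- numeric(0)
  for (layer in VASCULAR_LAYERS) {
    pars <- config$layer_params[[layer]]
    f <- smooth_field(shape, pars$texture_scale_px)
    p <- matrix(pars$base_vessel_fraction, shape[1L], shape[2L])
    p[lesion] <- p[lesion] * (1 - config$lesion_deficit[[layer]])
    if (layer %in% RETINAL_LAYERS) p[faz] <- 0
    perfused <- stats::pnorm(f) < p
    img <- config$background_intensity +
      perfused * (config$vessel_intensity - config$background_intensity)
    if (layer == "SVP" && any(vessels$mask))
      img[vessels$mask] <- config$svp_large_vessels$intensity
    noise <- stats::rnorm(prod(shape), sd = config$noise_sd)
    img <- if (isTRUE(config$speckle))
      img * exp(noise / pmax(img, 1)) else img + noise
    slabs[[layer]] <- slab_image(clip_to_8bit(img), layer, config$eye_id)
    for (region in names(region_masks)) {
      gt_frac <- c(gt_frac, mean(perfused[region_masks[[region]]]))
      gt_layer <- c(gt_layer, layer); gt_region <- c(gt_region, region)
      gt_base <- c(gt_base, pars$base_vessel_fraction)
      gt_deficit <- c(gt_deficit, config$lesion_deficit[[layer]])
    }
  }
  ir <- matrix(140, shape[1L], shape[2L])
  ir[faz] <- 128
  ir[lesion] <- 95                       # hyporeflective lesion
  ir <- ir + stats::rnorm(prod(shape), sd = 8)
  slabs$IR <- slab_image(clip_to_8bit(ir), "IR", config$eye_id)

  ground_truth <- data.frame(
    eye_id = config$eye_id, layer = gt_layer, region = gt_region,
    true_fraction = gt_frac, base_fraction = gt_base, deficit = gt_deficit,
    stringsAsFactors = FALSE)
  structure(list(slabs = slabs, label_mask = lm, regions = regions,
                 ground_truth = ground_truth,
                 large_vessel_truth = vessels$mask,
                 large_vessel_center_line = vessels$center_line,
                 config = config),
            class = "synthetic_eye")
}

#' Generate en-face IR/EZ/OPL lesion footprints
#'
#' The IR footprint is the configured lesion; the EZ footprint is the IR
#' footprint displaced by `ez_displacement_px` (0 by default, i.e.
#' identical); the OPL footprint is displaced by `opl_displacement_px` along
#' the ray from the fovea centre through the lesion centroid (or nasally,
#' i.e. horizontally, when configured), emulating the oblique course of the
#' Henle fibres.
#'
#' @param config a [synthetic_config()].
#' @return list with logical masks `ir`, `ez`, `opl` and `eye_id`.
#' @export
generate_enface <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    harmonics <- NULL
    if (config$lesion$shape == "blob")
      harmonics <- list(a = stats::rnorm(4), b = stats::rnorm(4))
    ir <- lesion_footprint(config$shape, config$lesion, harmonics)
    if (!any(ir))
      stop("invalid synthetic config: lesion footprint is empty", call. = FALSE)
    faz <- disk_mask(config$shape, config$fovea_center, config$faz_radius_px)
    if (any(ir & faz))
      stop("invalid synthetic config: lesion overlaps the FAZ", call. = FALSE)
    u <- if (config$displacement_direction == "nasal") c(0, 1) else {
      v <- mask_centroid(ir) - config$fovea_center
      v / sqrt(sum(v^2))
    }
    ez <- translate_mask(ir, round(config$ez_displacement_px * u))
    opl <- translate_mask(ir, round(config$opl_displacement_px * u))
    list(ir = ir, ez = ez, opl = opl, eye_id = config$eye_id)
  })
}

translate_mask <- function(mask, offset) {
  offset <- as.integer(offset)
  if (all(offset == 0L)) return(mask)
  idx <- which(mask, arr.ind = TRUE)
  dst <- cbind(idx[, 1L] + offset[1L], idx[, 2L] + offset[2L])
  if (any(dst[, 1L] < 1L | dst[, 1L] > nrow(mask) |
          dst[, 2L] < 1L | dst[, 2L] > ncol(mask)))
    stop("displacement pushes the lesion footprint out of frame", call. = FALSE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[dst] <- TRUE
  out
}

#' Displacement giving a target Dice score for a circular footprint
#'
#' Inverts the closed-form lens-area overlap of two equal circles of radius
#' `radius` to find the centre offset whose Dice score equals `target_dice`.
#' Used to calibrate en-face fixtures.
#'
#' @param radius circle radius (px).
#' @param target_dice desired Dice score in `(0, 1)`.
#' @return offset in pixels (continuous).
#' @export
displacement_for_dice <- function(radius, target_dice) {
  stopifnot(target_dice > 0, target_dice < 1, radius > 0)
  dice_of <- function(d) {
    u <- d / (2 * radius)
    lens <- 2 * radius^2 * acos(u) - (d / 2) * sqrt(4 * radius^2 - d^2)
    lens / (pi * radius^2)
  }
  stats::uniroot(function(d) dice_of(d) - target_dice,
                 lower = 1e-9, upper = 2 * radius - 1e-9,
                 tol = 1e-10)$root
}

#' Generate a jittered cohort of synthetic eyes
#'
#' Draws per-eye seeds and jitters the lesion geometry (semi-axes,
#' eccentricity, position angle) around `base_config`, keeping every lesion
#' outside the FAZ and inside the frame.
#'
#' @param n_eyes number of eyes, `>= 2`.
#' @param base_config a [synthetic_config()]; per-eye configs inherit
#'   everything except seed, eye id, and lesion geometry.
#' @param jitter list with `axes_frac`, `ecc_frac` (uniform relative jitter)
#'   and `angle_sd` (radians).
#' @param seed cohort-level seed (defaults to the base config's seed).
#' @param modality `"octa"` generates full eyes, `"enface"` only the en-face
#'   footprints, `"both"` generates both.
#' @return object of class `synthetic_cohort`: list with `eyes` and/or
#'   `enface`, plus `configs` and `seed`.
#' @export
generate_cohort <- function(n_eyes, base_config = synthetic_config(),
                            jitter = list(axes_frac = 0.15, ecc_frac = 0.10,
                                          angle_sd = 0.25),
                            seed = base_config$seed,
                            modality = c("octa", "enface", "both")) {
  modality <- match.arg(modality)
  if (n_eyes < 2L) stop("a cohort needs n_eyes >= 2", call. = FALSE)
  base <- min(base_config$shape)
  draws <- withr::with_seed(seed, list(
    eye_seeds = sample.int(.Machine$integer.max - 1L, n_eyes),
    axes = matrix(stats::runif(2L * n_eyes, 1 - jitter$axes_frac,
                               1 + jitter$axes_frac), ncol = 2L),
    ecc = stats::runif(n_eyes, 1 - jitter$ecc_frac, 1 + jitter$ecc_frac),
    ang = stats::rnorm(n_eyes, 0, jitter$angle_sd)))
  configs <- vector("list", n_eyes)
  for (i in seq_len(n_eyes)) {
    cfg <- base_config
    cfg$seed <- draws$eye_seeds[i]
    cfg$eye_id <- sprintf("eye%02d", i)
    les <- cfg$lesion
    les$axes <- les$axes * draws$axes[i, ]
    les$angle_pos <- les$angle_pos + draws$ang[i]
    ecc <- les$eccentricity_px * draws$ecc[i]
    max_ax <- max(les$axes) * (1 + les$irregularity)
    border <- min(cfg$fovea_center[1L] - 1, cfg$shape[1L] - cfg$fovea_center[1L],
                  cfg$fovea_center[2L] - 1, cfg$shape[2L] - cfg$fovea_center[2L])
    ecc <- max(ecc, cfg$faz_radius_px + max_ax + 2)     # keep clear of the FAZ
    ecc <- min(ecc, border - 2 * max_ax - 2)            # keep the ATC in frame
    les$eccentricity_px <- ecc
    les$center <- cfg$fovea_center + ecc * c(cos(les$angle_pos),
                                             sin(les$angle_pos))
    cfg$lesion <- les
    configs[[i]] <- cfg
  }
  out <- list(configs = configs, seed = seed, n_eyes = n_eyes)
  if (modality %in% c("octa", "both"))
    out$eyes <- lapply(configs, generate_eye)
  if (modality %in% c("enface", "both"))
    out$enface <- lapply(configs, generate_enface)
  structure(out, class = "synthetic_cohort")
}
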