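# On-disk artifacts: PNG slab exports, NIfTI conversion, ITK-Snap-style label
# maps, CSV result tables, and per-eye manifests.

OCTA_LAYERS     <- c("SVP", "ICP", "DCP", "CC", "CHOROID", "IR", "EZ", "OPL")
VASCULAR_LAYERS <- c("SVP", "ICP", "DCP", "CC", "CHOROID")
RETINAL_LAYERS  <- c("SVP", "ICP", "DCP")
REGION_NAMES    <- c("AMN", "ATC", "RS")

# ITU-R BT.601 luminance weights, fixed for the life of the package so that
# RGB-encoded grayscale exports always map to the same 8-bit values.
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

#' Construct a slab image
#'
#' A `slab_image` is one 2-D grayscale en-face image belonging to a named
#' vascular slab (SVP, ICP, DCP, CC, CHOROID) or auxiliary channel (IR, EZ,
#' OPL) of one eye. Intensities are 8-bit integers in `[0, 255]`. All slabs of
#' one eye are assumed co-registered, i.e. share dimensions; this is checked
#' wherever slabs are combined, never fixed by resampling.
#'
#' @param pixels integer matrix of intensities in `[0, 255]`.
#' @param layer one of `"SVP"`, `"ICP"`, `"DCP"`, `"CC"`, `"CHOROID"`,
#'   `"IR"`, `"EZ"`, `"OPL"` (case-insensitive).
#' @param eye_id opaque eye identifier.
#' @param pixel_pitch_um optional microns per pixel.
#' @return an object of class `slab_image`.
#' @export
slab_image <- function(pixels, layer, eye_id = "eye", pixel_pitch_um = NULL) {
  layer <- match.arg(toupper(as.character(layer)), OCTA_LAYERS)
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("slab intensities must all be finite", call. = FALSE)
  if (any(pixels < 0 | pixels > 255))
    stop("slab intensities must lie in [0, 255]", call. = FALSE)
  px <- pixels
  storage.mode(px) <- "integer"
  if (any(px != pixels))
    stop("slab intensities must be integers (8-bit export assumed)", call. = FALSE)
  structure(
    list(pixels = px, layer = layer, eye_id = eye_id,
         pixel_pitch_um = pixel_pitch_um),
    class = "slab_image"
  )
}

#' @export
print.slab_image <- function(x, ...) {
  cat(sprintf("<slab_image> %s / %s  %d x %d px  range [%d, %d]\n",
              x$eye_id, x$layer, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.slab_image <- function(x) dim(x$pixels)

# round-half-up, used everywhere a real-valued pixel quantity is snapped to an
# integer (R's round() is round-half-even, which is a poor fit for geometry
# that must be translation-equivariant)
round_half_up <- function(x) floor(x + 0.5)

#' Load an en-face slab from a PNG export
#'
#' Reads an 8-bit grayscale or RGB(A) PNG as exported from the device viewer.
#' RGB images are converted to grayscale with the ITU-R BT.601 luminance
#' transform `0.299 R + 0.587 G + 0.114 B` (rounded half-up to an integer);
#' any alpha channel is discarded.
#'
#' @param path path to a PNG file.
#' @inheritParams slab_image
#' @return a [slab_image()].
#' @export
load_slab_png <- function(path, layer, eye_id = "eye", pixel_pitch_um = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read slab PNG: '%s' does not exist", path), call. = FALSE)
  arr <- png::readPNG(path)
  if (length(arr) == 0L || any(dim(arr)[1:2] == 0L))
    stop(sprintf("zero-sized image in '%s'", path), call. = FALSE)
  px <- if (length(dim(arr)) == 2L) {
    round_half_up(arr * 255)
  } else {
    nc <- dim(arr)[3]
    if (nc == 2L) {                      # gray + alpha
      round_half_up(arr[, , 1L] * 255)
    } else {                             # RGB or RGBA
      r <- arr[, , 1L] * 255
      g <- arr[, , 2L] * 255
      b <- arr[, , 3L] * 255
      round_half_up(LUMA_WEIGHTS[1] * r + LUMA_WEIGHTS[2] * g + LUMA_WEIGHTS[3] * b)
    }
  }
  slab_image(px, layer = layer, eye_id = eye_id, pixel_pitch_um = pixel_pitch_um)
}

#' Write a slab image back to PNG
#'
#' @param image a [slab_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slab_png <- function(image, path) {
  stopifnot(inherits(image, "slab_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Convert an image or label map to NIfTI-1
#'
#' Writes a lossless integer (int16) NIfTI-1 file; a round-trip read
#' reproduces the pixel array exactly.
#'
#' @param image a [slab_image()] or [label_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
to_nifti <- function(image, path) {
  arr <- if (inherits(image, "slab_image")) image$pixels
         else if (inherits(image, "label_mask")) image$labels
         else if (is.matrix(image)) image
         else stop("`image` must be a slab_image, label_mask, or matrix", call. = FALSE)
  storage.mode(arr) <- "integer"
  RNifti::writeNifti(arr, path, datatype = "int16")
  invisible(path)
}

# read a 2-D NIfTI as an integer matrix
read_nifti_matrix <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read NIfTI: '%s' does not exist", path), call. = FALSE)
  arr <- as.array(RNifti::readNifti(path))
  arr <- drop(arr)
  if (length(dim(arr)) != 2L)
    stop(sprintf("'%s' is not a 2-D image", path), call. = FALSE)
  if (anyNA(arr) || any(arr != floor(arr)))
    stop(sprintf("'%s' contains non-integer data", path), call. = FALSE)
  matrix(as.integer(arr), nrow(arr), ncol(arr))
}

#' Construct a label mask
#'
#' Integer label map co-registered to the eye's IR image. The default label
#' convention follows the first two ITK-Snap labels: `1` = AMN lesion (red),
#' `2` = FAZ (green), `0` = background. Labels outside `label_meaning` are
#' tolerated and reported with a warning, then ignored by [mask_of()].
#'
#' @param labels integer matrix.
#' @param label_meaning named integer vector mapping region names to label
#'   values; must contain `AMN` and `FAZ`.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, label_meaning = c(background = 0, AMN = 1, FAZ = 2)) {
  if (!is.matrix(labels) || length(labels) == 0L)
    stop("`labels` must be a non-empty matrix", call. = FALSE)
  if (anyNA(labels) || any(labels != floor(labels)))
    stop("label map must contain integer labels", call. = FALSE)
  if (!all(c("AMN", "FAZ") %in% names(label_meaning)))
    stop("`label_meaning` must name AMN and FAZ labels", call. = FALSE)
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.vector(labels)))
  unknown <- setdiff(present, as.integer(label_meaning))
  if (length(unknown))
    warning(sprintf("ignoring unexpected label(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  obj <- structure(list(labels = labels, label_meaning = label_meaning),
                   class = "label_mask")
  if (any(mask_of(obj, "AMN") & mask_of(obj, "FAZ")))
    warning("AMN and FAZ labels overlap", call. = FALSE)  # unreachable for a
                                                          # true label map
  obj
}

#' @export
print.label_mask <- function(x, ...) {
  cnt <- vapply(names(x$label_meaning), function(nm) sum(mask_of(x, nm)), 0L)
  cat(sprintf("<label_mask> %d x %d px  %s\n", nrow(x$labels), ncol(x$labels),
              paste(sprintf("%s=%d px", names(cnt), cnt), collapse = "  ")))
  invisible(x)
}

#' @export
dim.label_mask <- function(x) dim(x$labels)

#' Binary mask of one label
#'
#' @param mask a [label_mask()].
#' @param label region name (e.g. `"AMN"`, `"FAZ"`) or integer label value.
#' @return logical matrix.
#' @export
mask_of <- function(mask, label) {
  stopifnot(inherits(mask, "label_mask"))
  value <- if (is.character(label)) {
    if (!label %in% names(mask$label_meaning))
      stop(sprintf("unknown label name '%s'", label), call. = FALSE)
    mask$label_meaning[[label]]
  } else as.integer(label)
  mask$labels == value
}

#' Load a label mask from NIfTI or PNG
#'
#' @param path path to a NIfTI (`.nii`/`.nii.gz`) or integer-valued PNG file.
#' @inheritParams label_mask
#' @return a [label_mask()].
#' @export
load_label_mask <- function(path, label_meaning = c(background = 0, AMN = 1, FAZ = 2)) {
  labels <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
    round_half_up(arr * 255)
  } else {
    read_nifti_matrix(path)
  }
  label_mask(labels, label_meaning = label_meaning)
}

# ---- result tables ---------------------------------------------------------

RESULT_SCHEMAS <- list(
  vad_records = c("eye_id", "layer", "region", "vad", "threshold",
                  "n_pixels", "n_excluded"),
  dice_records = c("eye_id", "pair", "dice", "area_a", "area_b",
                   "area_intersection"),
  cohort_results = c("layer", "comparator", "n_eyes", "mean_vad_amn",
                     "mean_vad_comparator", "percent_reduction", "t_stat",
                     "p_raw", "p_corrected", "m_comparisons")
)

detect_record_kind <- function(df) {
  hits <- names(RESULT_SCHEMAS)[vapply(RESULT_SCHEMAS,
                                       function(s) setequal(names(df), s),
                                       logical(1))]
  if (length(hits) != 1L)
    stop("unrecognised or mixed record kinds; expected a homogeneous table of ",
         "VAD, Dice, or cohort records", call. = FALSE)
  hits
}

#' Write a homogeneous results table to CSV
#'
#' Rows are sorted into a canonical, deterministic order (VAD records by eye,
#' slab, region; Dice records by eye and pair; cohort results by slab and
#' comparator) so repeated runs produce byte-identical files.
#'
#' @param records a data frame of VAD, Dice, or cohort records, or a list of
#'   such data frames of one kind (rows are bound together).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records) && length(records) > 0L) {
    kinds <- unique(vapply(records, detect_record_kind, character(1)))
    if (length(kinds) != 1L)
      stop("mixed record kinds in `records`", call. = FALSE)
    df <- do.call(rbind, records)
  } else {
    stop("`records` must be a data frame or non-empty list of data frames",
         call. = FALSE)
  }
  kind <- detect_record_kind(df)
  df <- df[, RESULT_SCHEMAS[[kind]], drop = FALSE]
  if (nrow(df) > 0L) {
    ord <- switch(kind,
      vad_records = order(df$eye_id, match(df$layer, VASCULAR_LAYERS),
                          match(df$region, REGION_NAMES)),
      dice_records = order(df$eye_id, df$pair),
      cohort_results = order(match(df$layer, VASCULAR_LAYERS), df$comparator))
    df <- df[ord, , drop = FALSE]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# ---- per-eye manifests -----------------------------------------------------

#' Read a per-eye manifest
#'
#' A manifest is a small YAML file mapping layer names to image paths:
#' \preformatted{
#' eye_id: eye01
#' pixel_pitch_um: 6
#' layers:
#'   SVP: svp.png
#'   ICP: icp.png
#'   DCP: dcp.png
#'   CC: cc.png
#'   CHOROID: choroid.png
#'   IR: ir.png
#' labels: labels.nii.gz
#' }
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest YAML path.
#' @return named list with `eye_id`, `pixel_pitch_um`, `layers`, `labels`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest '%s' does not exist", path), call. = FALSE)
  man <- yaml::read_yaml(path)
  if (is.null(man$layers) || is.null(man$eye_id))
    stop("manifest must provide `eye_id` and `layers`", call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  man$layers <- lapply(man$layers, resolve)
  if (!is.null(man$labels)) man$labels <- resolve(man$labels)
  man
}

#' Load all images of one eye from a manifest
#'
#' Checks co-registration by shape: every slab and the label map must share
#' dimensions. No resampling is ever performed.
#'
#' @param path manifest YAML path.
#' @inheritParams label_mask
#' @return list with `slabs` (named list of [slab_image()]), `labels`
#'   (a [label_mask()] or `NULL`), `eye_id`, `pixel_pitch_um`.
#' @export
load_eye <- function(path, label_meaning = c(background = 0, AMN = 1, FAZ = 2)) {
  man <- read_manifest(path)
  slabs <- lapply(names(man$layers), function(layer) {
    p <- man$layers[[layer]]
    if (grepl("\\.png$", p, ignore.case = TRUE))
      load_slab_png(p, layer = layer, eye_id = man$eye_id,
                    pixel_pitch_um = man$pixel_pitch_um)
    else
      slab_image(read_nifti_matrix(p), layer = layer, eye_id = man$eye_id,
                 pixel_pitch_um = man$pixel_pitch_um)
  })
  names(slabs) <- toupper(names(man$layers))
  dims <- vapply(slabs, function(s) dim(s$pixels), integer(2))
  if (length(slabs) > 1L && any(dims != dims[, 1L]))
    stop("co-registration error: slabs of one eye differ in dimensions",
         call. = FALSE)
  labels <- NULL
  if (!is.null(man$labels)) {
    labels <- load_label_mask(man$labels, label_meaning = label_meaning)
    if (!identical(dim(labels$labels), unname(dims[, 1L])))
      stop("co-registration error: label map dimensions differ from the slabs",
           call. = FALSE)
  }
  list(slabs = slabs, labels = labels, eye_id = man$eye_id,
       pixel_pitch_um = man$pixel_pitch_um)
}
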