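# Convenience orchestration: run the per-eye quantification across a cohort
# and write the artifacts the CLI exposes.

#' Quantify every eye of a synthetic cohort
#'
#' Rebuilds the comparator regions from each eye's label mask (the same path
#' a real analysis takes) and runs [quantify_eye()].
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()] (with
#'   `modality` `"octa"` or `"both"`).
#' @param config a [quantify_config()].
#' @param atc_scale linear ATC scale factor.
#' @return `vad_records` data frame with 15 rows per eye.
#' @export
quantify_cohort <- function(cohort, config = quantify_config(), atc_scale = 2) {
  stopifnot(inherits(cohort, "synthetic_cohort"), !is.null(cohort$eyes))
  rows <- lapply(cohort$eyes, function(eye) {
    regions <- region_set(eye$label_mask, atc_scale = atc_scale)
    quantify_eye(eye$slabs, regions, config = config)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("vad_records", class(out))
  out
}

#' En-face Dice records for every eye of a cohort
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()] (with
#'   `modality` `"enface"` or `"both"`).
#' @return `dice_records` data frame with two rows per eye.
#' @export
dice_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"), !is.null(cohort$enface))
  out <- do.call(rbind, lapply(cohort$enface, function(e)
    enface_overlap_analysis(e$ir, e$ez, e$opl, eye_id = e$eye_id)))
  class(out) <- c("dice_records", class(out))
  out
}

#' Write a synthetic eye to disk in the analysis input formats
#'
#' Writes each slab as PNG, the label mask and large-vessel ground truth as
#' NIfTI, the ground-truth table as CSV, and a manifest consumable by
#' [load_eye()].
#'
#' @param eye a `synthetic_eye` from [generate_eye()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_eye <- function(eye, dir) {
  stopifnot(inherits(eye, "synthetic_eye"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layer_files <- list()
  for (layer in names(eye$slabs)) {
    fn <- paste0(tolower(layer), ".png")
    write_slab_png(eye$slabs[[layer]], file.path(dir, fn))
    layer_files[[layer]] <- fn
  }
  to_nifti(eye$label_mask, file.path(dir, "labels.nii.gz"))
  to_nifti(matrix(as.integer(eye$large_vessel_truth),
                  nrow(eye$large_vessel_truth)),
           file.path(dir, "large_vessel_truth.nii.gz"))
  utils::write.csv(eye$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(eye_id = eye$config$eye_id,
                        pixel_pitch_um = 6,
                        layers = layer_files,
                        labels = "labels.nii.gz"),
                   manifest)
  invisible(manifest)
}
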