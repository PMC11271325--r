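# Sorensen-Dice overlap between the IR lesion segmentation and lesion
# segmentations on en-face OCT reconstructions at the EZ and OPL levels.

#' Sorensen-Dice score of two binary masks
#'
#' `dice = 2 |A intersect B| / (|A| + |B|)`. Masks are taken literally (no
#' morphological cleanup). The score is 1 exactly when the masks are
#' identical and 0 exactly when they are disjoint; both masks empty is
#' undefined and raises an error.
#'
#' @param mask_a,mask_b logical matrices of identical dimensions.
#' @param eye_id,pair identifiers stored in the record.
#' @return one-row data frame (a Dice record) with columns `eye_id`, `pair`,
#'   `dice`, `area_a`, `area_b`, `area_intersection`.
#' @export
dice_score <- function(mask_a, mask_b, eye_id = "eye", pair = NA_character_) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must share dimensions", call. = FALSE)
  a <- sum(mask_a); b <- sum(mask_b)
  if (a + b == 0L)
    stop("both masks empty: Dice score undefined", call. = FALSE)
  i <- sum(mask_a & mask_b)
  data.frame(eye_id = eye_id, pair = pair, dice = 2 * i / (a + b),
             area_a = a, area_b = b, area_intersection = i,
             stringsAsFactors = FALSE)
}

#' En-face overlap analysis for one eye
#'
#' Scores the EZ-level and OPL-level en-face lesion segmentations against the
#' IR lesion segmentation.
#'
#' @param ir_lesion,ez_lesion,opl_lesion co-registered logical lesion masks.
#' @param eye_id eye identifier.
#' @return data frame of two Dice records (`EZ_vs_IR`, `OPL_vs_IR`) of class
#'   `dice_records`.
#' @export
enface_overlap_analysis <- function(ir_lesion, ez_lesion, opl_lesion,
                                    eye_id = "eye") {
  out <- rbind(
    dice_score(ez_lesion, ir_lesion, eye_id = eye_id, pair = "EZ_vs_IR"),
    dice_score(opl_lesion, ir_lesion, eye_id = eye_id, pair = "OPL_vs_IR")
  )
  class(out) <- c("dice_records", class(out))
  out
}

#' Paired comparison of EZ-vs-IR and OPL-vs-IR Dice scores across eyes
#'
#' @param records Dice records from [enface_overlap_analysis()] for two or
#'   more eyes (rows bound together).
#' @return list with per-pair mean and sd, the paired t statistic, and the
#'   two-sided p-value.
#' @export
compare_dice_pairs <- function(records) {
  stopifnot(is.data.frame(records), all(c("eye_id", "pair", "dice") %in% names(records)))
  ez  <- records[records$pair == "EZ_vs_IR", c("eye_id", "dice")]
  opl <- records[records$pair == "OPL_vs_IR", c("eye_id", "dice")]
  eyes <- intersect(ez$eye_id, opl$eye_id)
  if (length(eyes) < 2L)
    stop("insufficient eyes: need >= 2 eyes with both Dice pairs", call. = FALSE)
  a <- ez$dice[match(eyes, ez$eye_id)]
  b <- opl$dice[match(eyes, opl$eye_id)]
  tt <- paired_t_test(a, b)
  list(n_eyes = length(eyes),
       mean_dice_ez = mean(a), sd_dice_ez = stats::sd(a),
       mean_dice_opl = mean(b), sd_dice_opl = stats::sd(b),
       t_stat = tt$t_stat, p_value = tt$p_raw)
}
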