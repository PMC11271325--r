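# Cohort statistics: paired t-tests with explicit Bonferroni correction,
# percent reductions, and the per-slab summary table.

#' Two-sided paired t-test
#'
#' Thin wrapper around [stats::t.test()] with the degenerate case surfaced
#' explicitly: when all paired differences are identical the test statistic
#' is undefined and an error is raised rather than returning p = 0.
#'
#' @param a,b numeric vectors of per-eye values, equal length `n >= 2`.
#' @return list with `t_stat`, `df`, `p_raw`, `mean_diff`, `n`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2L)
    stop("insufficient eyes: paired test needs n >= 2", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("degenerate differences: all paired differences are identical",
         call. = FALSE)
  if (n == 2L)
    warning("paired t-test with n = 2 (df = 1) has almost no power",
            call. = FALSE)
  tt <- tryCatch(
    stats::t.test(a, b, paired = TRUE, alternative = "two.sided"),
    error = function(e)
      stop("degenerate differences: ", conditionMessage(e), call. = FALSE)
  )
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = tt$p.value, mean_diff = unname(tt$estimate), n = n)
}

#' Bonferroni correction with explicit family size
#'
#' `min(1, m * p)`, delegated to [stats::p.adjust()]. The family size `m` is
#' an explicit argument (and is recorded in every [summarize_cohort()] row)
#' so that any reproduction states its multiplicity choice.
#'
#' @param p_raw raw p-value(s) in `[0, 1]`.
#' @param m number of comparisons in the family, `>= 1`.
#' @return corrected p-value(s), capped at 1.
#' @export
bonferroni <- function(p_raw, m) {
  if (any(p_raw < 0 | p_raw > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < 1 || m != floor(m)) stop("`m` must be a positive integer", call. = FALSE)
  if (m < length(p_raw)) return(pmin(1, m * p_raw))
  unname(stats::p.adjust(p_raw, method = "bonferroni", n = m))
}

#' Summarise a cohort of per-eye VAD records
#'
#' For each of the five vascular slabs and each comparator region (ATC, RS),
#' runs a two-sided paired t-test of per-eye lesion VAD against comparator
#' VAD, computes the percent reduction, and applies Bonferroni correction
#' with the stated family size.
#'
#' @param records VAD records for all eyes ([quantify_eye()] rows bound
#'   together); every eye must contribute all 15 records.
#' @param m_comparisons Bonferroni family size. The default 10 treats the 5
#'   slabs x 2 comparators as one family.
#' @param reduction `"of_means"` (default): percent reduction of cohort
#'   means, `100 (mean_comp - mean_amn) / mean_comp`; `"per_eye"`: mean of
#'   per-eye percent reductions.
#' @return data frame of 10 rows of class `cohort_results`.
#' @export
summarize_cohort <- function(records, m_comparisons = 10L,
                             reduction = c("of_means", "per_eye")) {
  reduction <- match.arg(reduction)
  stopifnot(is.data.frame(records))
  eyes <- sort(unique(records$eye_id))
  if (length(eyes) < 2L)
    stop("insufficient eyes: cohort statistics need >= 2 eyes", call. = FALSE)
  for (eye in eyes) {
    sub <- records[records$eye_id == eye, ]
    want <- expand.grid(layer = VASCULAR_LAYERS, region = REGION_NAMES,
                        stringsAsFactors = FALSE)
    have <- paste(sub$layer, sub$region)
    if (nrow(sub) != 15L || !setequal(have, paste(want$layer, want$region)))
      stop(sprintf("incomplete eye: '%s' lacks some of the 15 slab x region records",
                   eye), call. = FALSE)
  }
  vad_of <- function(layer, region)
    vapply(eyes, function(eye)
      records$vad[records$eye_id == eye & records$layer == layer &
                  records$region == region][1L], numeric(1))
  rows <- list()
  for (layer in VASCULAR_LAYERS) {
    a <- vad_of(layer, "AMN")
    for (comparator in c("ATC", "RS")) {
      b <- vad_of(layer, comparator)
      tt <- paired_t_test(a, b)
      pct <- switch(reduction,
        of_means = if (mean(b) > 0) 100 * (mean(b) - mean(a)) / mean(b) else NA_real_,
        per_eye  = mean(ifelse(b > 0, 100 * (b - a) / b, NA_real_)))
      rows[[length(rows) + 1L]] <- data.frame(
        layer = layer, comparator = comparator, n_eyes = length(eyes),
        mean_vad_amn = mean(a), mean_vad_comparator = mean(b),
        percent_reduction = pct, t_stat = tt$t_stat, p_raw = tt$p_raw,
        p_corrected = bonferroni(tt$p_raw, m_comparisons),
        m_comparisons = as.integer(m_comparisons), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_results", class(out))
  out
}
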