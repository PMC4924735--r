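#' Modified H-score for staining intensity fractions
#'
#' `%weak + 2 * %moderate + 3 * %strong`, ranging from 0 (no staining) to
#' 300 (every cell strongly stained). Vectorized over samples.
#'
#' @param pct_weak,pct_moderate,pct_strong Percentages of cells staining at
#'   each intensity, each in 0-100, summing to at most 100.
#' @return Numeric H-score(s) in \[0, 300\].
#' @examples
#' h_score(20, 30, 10) # 110
#' @export
h_score <- function(pct_weak, pct_moderate, pct_strong) {
  pcts <- cbind(pct_weak, pct_moderate, pct_strong)
  if (any(pcts < 0 | pcts > 100, na.rm = TRUE)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  tot <- pct_weak + pct_moderate + pct_strong
  if (any(tot > 100 + 1e-9, na.rm = TRUE)) {
    stop("staining percentages sum above 100", call. = FALSE)
  }
  pct_weak + 2 * pct_moderate + 3 * pct_strong
}

#' Hot-spot positive-cell count
#'
#' For markers staining scattered single cells, the score is the count in
#' the high-power field with the highest density of positive cells, i.e. the
#' maximum over the evaluated fields.
#'
#' @param per_field_counts Non-negative integer counts, one per field
#'   (non-empty).
#' @return The maximum count.
#' @export
pttg1_hotspot_count <- function(per_field_counts) {
  if (length(per_field_counts) == 0) {
    stop("no fields counted", call. = FALSE)
  }
  if (any(per_field_counts < 0 |
          per_field_counts != round(per_field_counts), na.rm = TRUE)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  max(per_field_counts)
}

#' Combined two-marker IHC score
#'
#' `pttg1_count * 100 / lepr_h_score`: rises with the hazard-increasing
#' marker and falls with the protective one, so aggressive tumors score
#' high. Undefined (`NA`) when the H-score denominator is 0; a plotting
#' ceiling can be substituted downstream.
#'
#' @param pttg1_count Non-negative hot-spot count(s).
#' @param lepr_h_score H-score(s) in \[0, 300\].
#' @return Numeric combined score(s); `NA` where `lepr_h_score` is 0.
#' @export
combined_ihc_score <- function(pttg1_count, lepr_h_score) {
  if (any(lepr_h_score < 0, na.rm = TRUE)) {
    stop("H-score must be non-negative", call. = FALSE)
  }
  ifelse(lepr_h_score == 0, NA_real_, pttg1_count * 100 / lepr_h_score)
}

#' Score an IHC table and summarize by subgroup
#'
#' Computes per-sample H-scores and combined scores from an `IhcTable`, and
#' (when an annotation is supplied) per-category means with standard errors,
#' the usual presentation of subgroup staining results.
#'
#' @param tbl An `IhcTable` (see [ihc_table()]).
#' @param ann Optional `SampleAnnotation` for subgroup summaries.
#' @return List with `scores` (per-sample data.frame: `sample_id`,
#'   `h_score`, `pttg1_count`, `combined_score`) and, when annotated,
#'   `by_subgroup` (category, n, mean, sem of the combined score).
#' @export
ihc_scores <- function(tbl, ann = NULL) {
  hs <- h_score(tbl$pct_weak, tbl$pct_moderate, tbl$pct_strong)
  scores <- data.frame(sample_id = tbl$sample_id, h_score = hs,
                       pttg1_count = tbl$pttg1_count,
                       combined_score = combined_ihc_score(tbl$pttg1_count, hs),
                       stringsAsFactors = FALSE)
  out <- list(scores = scores)
  if (!is.null(ann)) {
    idx <- match(scores$sample_id, ann$sample_id)
    grade_num <- c(I = "1", II = "2", III = "3")
    category <- ifelse(is.na(idx), "unknown",
                       paste0(grade_num[ann$who_grade[idx]],
                              ann$subgroup[idx]))
    cs <- scores$combined_score
    by <- lapply(split(cs, category), function(v) {
      v <- v[!is.na(v)]
      c(n = length(v), mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))
    })
    out$by_subgroup <- data.frame(category = names(by),
                                  do.call(rbind, by), row.names = NULL)
  }
  out
}
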