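#' Classify the expression change between a matched primary/recurrent pair
#'
#' The ratio is recurrent over primary expression on the linear scale. An
#' increase is a ratio of at least 2, a decrease a ratio of at most 0.5
#' (both thresholds inclusive); anything in between is stable.
#'
#' @param primary_value,recurrent_value Positive linear-scale expression
#'   values.
#' @return List with `ratio` and `category`
#'   (`"increase"`/`"decrease"`/`"stable"`).
#' @export
classify_pair_change <- function(primary_value, recurrent_value) {
  if (any(c(primary_value, recurrent_value) <= 0) ||
      any(!is.finite(c(primary_value, recurrent_value)))) {
    stop("expression values must be positive and finite", call. = FALSE)
  }
  ratio <- recurrent_value / primary_value
  category <- if (ratio >= 2) "increase" else if (ratio <= 0.5) "decrease"
  else "stable"
  list(ratio = ratio, category = category)
}

#' Build the per-pair change table from longitudinal samples
#'
#' Takes a long-format table of per-patient tumor samples at successive
#' surgical time points and classifies, per gene, the change between paired
#' samples. By default consecutive time points are paired (first vs next,
#' second vs third, ...); `pairing = "first_last"` compares only the first
#' and last sample of each patient.
#'
#' @param values Data.frame with columns `patient_id`, `timepoint` (sortable;
#'   1 = primary), `gene`, `value` (positive, linear scale).
#' @param progression Named character vector mapping patient id to
#'   `"stable_who"` or `"increasing_who"`.
#' @param pairing `"consecutive"` (default) or `"first_last"`.
#' @return A `PairChange` data.frame: `patient_id`, `gene`, `ratio`,
#'   `category`, `progression_group`.
#' @export
pair_changes <- function(values, progression,
                         pairing = c("consecutive", "first_last")) {
  pairing <- match.arg(pairing)
  need <- c("patient_id", "timepoint", "gene", "value")
  missing_cols <- setdiff(need, names(values))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (pid in unique(values$patient_id)) {
    pv <- values[values$patient_id == pid, ]
    tps <- sort(unique(pv$timepoint))
    if (length(tps) < 2) next
    steps <- if (pairing == "consecutive") {
      Map(c, tps[-length(tps)], tps[-1])
    } else {
      list(c(tps[1], tps[length(tps)]))
    }
    for (g in unique(pv$gene)) {
      for (st in steps) {
        v1 <- pv$value[pv$timepoint == st[1] & pv$gene == g]
        v2 <- pv$value[pv$timepoint == st[2] & pv$gene == g]
        if (length(v1) != 1 || length(v2) != 1 || is.na(v1) || is.na(v2)) next
        cl <- classify_pair_change(v1, v2)
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = pid, gene = g, ratio = cl$ratio,
          category = cl$category,
          progression_group = unname(progression[as.character(pid)]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(patient_id = character(0), gene = character(0),
                      ratio = numeric(0), category = character(0),
                      progression_group = character(0))
  }
  class(res) <- c("PairChange", "data.frame")
  res
}

#' Summarize pair-change categories by gene and progression group
#'
#' Counts increase/decrease/stable calls per gene, split by whether the
#' patient's WHO grade stayed stable or increased at recurrence. Per gene,
#' the counts partition the pairs with data.
#'
#' @param pairs A `PairChange` data.frame from [pair_changes()].
#' @param genes Optional subset of genes to tabulate.
#' @return Data.frame with `gene`, `progression_group`, `increase`,
#'   `decrease`, `stable`, `n`.
#' @export
summarize_patterns <- function(pairs, genes = NULL) {
  if (!is.null(genes)) pairs <- pairs[pairs$gene %in% genes, ]
  if (nrow(pairs) == 0) {
    return(data.frame(gene = character(0), progression_group = character(0),
                      increase = integer(0), decrease = integer(0),
                      stable = integer(0), n = integer(0)))
  }
  agg <- expand.grid(gene = unique(pairs$gene),
                     progression_group = unique(pairs$progression_group),
                     stringsAsFactors = FALSE)
  count_cat <- function(g, pg, cat) {
    sum(pairs$gene == g & pairs$progression_group == pg &
          pairs$category == cat)
  }
  agg$increase <- mapply(count_cat, agg$gene, agg$progression_group,
                         "increase")
  agg$decrease <- mapply(count_cat, agg$gene, agg$progression_group,
                         "decrease")
  agg$stable <- mapply(count_cat, agg$gene, agg$progression_group, "stable")
  agg$n <- agg$increase + agg$decrease + agg$stable
  agg
}
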