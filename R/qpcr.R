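#' Relative expression from Cq replicates against housekeeping genes
#'
#' Computes the relative quantity `efficiency^(ref_cq - mean(target_cq))`,
#' where `ref_cq` is the arithmetic mean over the housekeeping genes of
#' their per-gene replicate-mean Cq. Averaging Cq values (log-scale
#' quantities) is equivalent to taking the geometric mean of the linear
#' quantities, the standard way to combine two reference genes. With the
#' default efficiency of 2 a target one cycle below the reference doubles
#' the value.
#'
#' @param target_cq Numeric vector of Cq replicates for the target gene.
#' @param hk_cq List of numeric vectors, one per housekeeping gene.
#' @param efficiency Amplification efficiency per cycle (> 1, default 2).
#' @return List with `value` (positive relative quantity, or `NA` when all
#'   target replicates are missing), `replicate_cv` (coefficient of
#'   variation of the target replicates) and `ref_cq`.
#' @examples
#' relative_expression(c(24, 24, 24), list(ACTB = c(20, 20, 20),
#'                                         GNB1 = c(22, 22, 22)))$value # 0.125
#' @export
relative_expression <- function(target_cq, hk_cq, efficiency = 2) {
  if (efficiency <= 1) stop("efficiency must exceed 1", call. = FALSE)
  target_cq <- target_cq[!is.na(target_cq)]
  if (length(target_cq) == 0) {
    return(list(value = NA_real_, replicate_cv = NA_real_,
                ref_cq = NA_real_))
  }
  hk_means <- vapply(hk_cq, function(x) mean(x, na.rm = TRUE), numeric(1))
  if (any(!is.finite(hk_means))) {
    stop("housekeeping Cq values missing", call. = FALSE)
  }
  ref_cq <- mean(hk_means)
  m <- mean(target_cq)
  list(value = efficiency^(ref_cq - m),
       replicate_cv = stats::sd(target_cq) / m,
       ref_cq = ref_cq)
}

#' Relative expression for every sample and target gene of a Cq table
#'
#' Applies [relative_expression()] across a long-format `QpcrTable`, using
#' the table's housekeeping genes as the per-sample reference.
#'
#' @param tbl A `QpcrTable` (see [qpcr_table()]).
#' @param efficiency Amplification efficiency (default 2).
#' @return Data.frame with `sample_id`, `gene`, `value`, `replicate_cv`.
#' @export
qpcr_relative_expression <- function(tbl, efficiency = 2) {
  hk <- attr(tbl, "housekeeping")
  targets <- setdiff(unique(tbl$gene), hk)
  rows <- list()
  for (s in unique(tbl$sample_id)) {
    sub <- tbl[tbl$sample_id == s, ]
    hk_cq <- lapply(hk, function(g) sub$cq[sub$gene == g])
    names(hk_cq) <- hk
    if (any(lengths(hk_cq) == 0)) {
      stop("sample ", s, " lacks Cq values for housekeeping gene(s): ",
           paste(hk[lengths(hk_cq) == 0], collapse = ", "), call. = FALSE)
    }
    for (g in targets) {
      cq <- sub$cq[sub$gene == g]
      if (length(cq) == 0) next
      re <- relative_expression(cq, hk_cq, efficiency)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, gene = g, value = re$value,
        replicate_cv = re$replicate_cv, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' Two-sided rank-sum test. For small samples (both groups at most
#' `exact_max` and no ties) the exact distribution is used; otherwise the
#' normal approximation with tie correction. With all pooled values tied the
#' test is uninformative and p is 1.
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @param exact_max Largest per-group size for the exact p (default 8).
#' @return List with `U` (the rank-sum statistic for the first group) and
#'   `p_value`.
#' @export
mann_whitney_compare <- function(values_a, values_b, exact_max = 8) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1) {
    return(list(U = length(values_a) * length(values_b) / 2, p_value = 1))
  }
  has_ties <- any(duplicated(pooled))
  use_exact <- !has_ties && length(values_a) <= exact_max &&
    length(values_b) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = use_exact,
                       correct = !use_exact))
  list(U = unname(ht$statistic), p_value = ht$p.value)
}

#' Subgroup comparisons of qPCR relative expression
#'
#' For each gene, compares relative expression between two sample groups
#' with [mann_whitney_compare()].
#'
#' @param rel Data.frame from [qpcr_relative_expression()].
#' @param group_a,group_b Character vectors of sample ids.
#' @param name_a,name_b Labels for the output.
#' @return Data.frame with one row per gene: group medians, U and p.
#' @export
qpcr_compare_groups <- function(rel, group_a, group_b,
                                name_a = "A", name_b = "B") {
  out <- lapply(unique(rel$gene), function(g) {
    va <- rel$value[rel$gene == g & rel$sample_id %in% group_a]
    vb <- rel$value[rel$gene == g & rel$sample_id %in% group_b]
    va <- va[!is.na(va)]
    vb <- vb[!is.na(vb)]
    if (length(va) == 0 || length(vb) == 0) return(NULL)
    mw <- mann_whitney_compare(va, vb)
    data.frame(gene = g, median_a = stats::median(va),
               median_b = stats::median(vb), n_a = length(va),
               n_b = length(vb), U = mw$U, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "groups") <- c(name_a, name_b)
  res
}
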