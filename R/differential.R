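#' Define a two-group comparison
#'
#' Pairs two disjoint sets of sample ids (typically selected with
#' [select_samples()]) with the significance and fold-change thresholds used
#' when the comparison's gene list is derived.
#'
#' @param name Comparison label, e.g. `"1M+R vs 1NR"`.
#' @param group_a,group_b Character vectors of sample ids; must be disjoint
#'   and non-empty.
#' @param p_threshold Two-sided p-value cutoff (strict `<`), default 0.01.
#' @param fc_threshold Linear fold-change cutoff (> 1), applied two-sidedly:
#'   a gene passes when its fold change exceeds `fc_threshold` or falls below
#'   `1/fc_threshold`. Default 1.25.
#' @return A `ComparisonSpec` list.
#' @export
comparison_spec <- function(name, group_a, group_b,
                            p_threshold = 0.01, fc_threshold = 1.25) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (p_threshold <= 0 || fc_threshold <= 1) {
    stop("need p_threshold > 0 and fc_threshold > 1", call. = FALSE)
  }
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 p_threshold = p_threshold, fc_threshold = fc_threshold),
            class = "ComparisonSpec")
}

#' Select sample ids by WHO grade and clinico-pathological subgroup
#'
#' @param ann A `SampleAnnotation` data.frame.
#' @param who Optional WHO grades to keep (subset of `"I"`, `"II"`, `"III"`).
#' @param subgroup Optional subgroups to keep (subset of `"NR"`, `"R"`,
#'   `"M"`, `"NA"`).
#' @return Character vector of matching sample ids.
#' @examples
#' \dontrun{
#' aggressive_I <- select_samples(ann, who = "I", subgroup = c("M", "R"))
#' }
#' @export
select_samples <- function(ann, who = NULL, subgroup = NULL) {
  keep <- rep(TRUE, nrow(ann))
  if (!is.null(who)) keep <- keep & ann$who_grade %in% who
  if (!is.null(subgroup)) keep <- keep & ann$subgroup %in% subgroup
  ann$sample_id[keep]
}

# internal vectorized pooled-variance t-test over the rows of a matrix;
# a tiny variance floor guards constant genes in synthetic fixtures
row_t_pooled <- function(a, b, var_floor = 1e-12) {
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2)
  vb <- rowSums((b - mb)^2)
  df <- na + nb - 2
  sp2 <- (va + vb) / df + var_floor
  tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tt), df)
  # equal means on a constant gene: no evidence, p = 1
  p[va + vb == 0 & ma == mb] <- 1
  list(mean_a = ma, mean_b = mb, t = tt, df = df, p = p,
       degenerate = va + vb == 0)
}

#' Per-gene two-group differential expression (pooled t-test)
#'
#' Runs Student's pooled-variance two-sided t-test for every gene between
#' two sample groups of a log2-scale matrix. The log2 difference is
#' `mean(A) - mean(B)` and the linear fold change is `2^delta_log2`, so
#' swapping the groups negates the statistic and inverts the fold change.
#'
#' @param em Log2-scale `ExpressionMatrix`.
#' @param spec A `ComparisonSpec`, or `NULL` if `group_a`/`group_b` are given
#'   directly.
#' @param group_a,group_b Character vectors of sample ids (ignored when
#'   `spec` is supplied). Each group needs at least 2 samples.
#' @return A `DifferentialResult` data.frame with columns `gene`,
#'   `mean_log2_a`, `mean_log2_b`, `delta_log2`, `fold_change_linear`,
#'   `t_statistic`, `df`, `p_value`, `degenerate`.
#' @export
t_test_de <- function(em, spec = NULL, group_a = NULL, group_b = NULL) {
  check_scale(em, "log2", "t_test_de")
  if (!is.null(spec)) {
    group_a <- spec$group_a
    group_b <- spec$group_b
  }
  miss <- setdiff(c(group_a, group_b), colnames(em$values))
  if (length(miss) > 0) {
    stop("sample id(s) not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  a <- em$values[, group_a, drop = FALSE]
  b <- em$values[, group_b, drop = FALSE]
  st <- row_t_pooled(a, b)
  delta <- st$mean_a - st$mean_b
  res <- data.frame(gene = rownames(em$values),
                    mean_log2_a = st$mean_a, mean_log2_b = st$mean_b,
                    delta_log2 = delta, fold_change_linear = 2^delta,
                    t_statistic = st$t, df = st$df, p_value = st$p,
                    degenerate = st$degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("DifferentialResult", "data.frame")
  res
}

# internal: count genes passing both the p and the two-sided FC threshold
count_passing <- function(p, delta_log2, p_threshold, fc_threshold) {
  fc <- 2^delta_log2
  sum(p < p_threshold & (fc > fc_threshold | fc < 1 / fc_threshold))
}

#' Permutation-based FDR for a thresholded differential gene list
#'
#' Estimates the false discovery rate of the set of genes passing both a
#' p-value and a (two-sided) fold-change threshold, by permuting the group
#' labels: under each permutation the number of threshold-passing genes is
#' counted, and the FDR estimate is the median null count divided by the
#' observed count (the mean is available as an option). The ratio is capped
#' at 1; the uncapped ratio is also returned. With an observed count of 0
#' the estimate is undefined (`NA`) rather than a division error.
#'
#' @param em Log2-scale `ExpressionMatrix`.
#' @param group_a,group_b Sample id vectors (each >= 2 samples).
#' @param p_threshold,fc_threshold Thresholds as in [comparison_spec()].
#' @param n_perm Number of label permutations (default 1000, minimum 10).
#' @param seed Integer seed; the same seed yields the identical estimate.
#' @param null_summary `"median"` (default) or `"mean"` of the null counts.
#' @return A list: `fdr`, `fdr_uncapped`, `observed_count`, `null_counts`,
#'   `n_perm`.
#' @export
permutation_fdr <- function(em, group_a, group_b,
                            p_threshold = 0.01, fc_threshold = 1.25,
                            n_perm = 1000, seed = 1,
                            null_summary = c("median", "mean")) {
  check_scale(em, "log2", "permutation_fdr")
  null_summary <- match.arg(null_summary)
  if (n_perm < 10) stop("n_perm must be at least 10", call. = FALSE)
  vals <- em$values[, c(group_a, group_b), drop = FALSE]
  na <- length(group_a)
  n <- ncol(vals)
  if (na < 2 || n - na < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  obs <- row_t_pooled(vals[, seq_len(na), drop = FALSE],
                      vals[, -seq_len(na), drop = FALSE])
  observed <- count_passing(obs$p, obs$mean_a - obs$mean_b,
                            p_threshold, fc_threshold)
  if (!is.null(seed)) set.seed(seed)
  null_counts <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    st <- row_t_pooled(vals[, idx, drop = FALSE],
                       vals[, -idx, drop = FALSE])
    null_counts[i] <- count_passing(st$p, st$mean_a - st$mean_b,
                                    p_threshold, fc_threshold)
  }
  null_stat <- if (null_summary == "median") stats::median(null_counts) else
    mean(null_counts)
  ratio <- if (observed == 0) NA_real_ else null_stat / observed
  list(fdr = if (is.na(ratio)) NA_real_ else min(1, ratio),
       fdr_uncapped = ratio, observed_count = observed,
       null_counts = null_counts, n_perm = n_perm)
}
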