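#' Threshold a differential result into up/down gene lists
#'
#' Applies the printed cutoffs with strict inequalities: a gene is "up" when
#' `p < p_threshold` and its linear fold change exceeds `fc_threshold`, and
#' "down" when `p < p_threshold` and the fold change falls below
#' `1/fc_threshold`. The two sets are disjoint by construction.
#'
#' @param results A `DifferentialResult` data.frame from [t_test_de()].
#' @param p_threshold Strict p-value cutoff.
#' @param fc_threshold Linear fold-change cutoff (> 1).
#' @return A list with character vectors `up` and `down`.
#' @export
de_gene_list <- function(results, p_threshold = 0.01, fc_threshold = 1.25) {
  if (nrow(results) == 0) return(list(up = character(0), down = character(0)))
  sig <- results$p_value < p_threshold
  list(up = results$gene[sig & results$fold_change_linear > fc_threshold],
       down = results$gene[sig & results$fold_change_linear < 1 / fc_threshold])
}

# internal: label the 7 regions of a 3-set Venn diagram for one direction
venn_regions <- function(sets) {
  stopifnot(length(sets) == 3)
  nms <- names(sets)
  all_genes <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  if (length(all_genes) == 1) membership <- matrix(membership, nrow = 1)
  region <- apply(membership, 1, function(m) paste(nms[m], collapse = "&"))
  counts <- integer(7)
  labels <- c(nms,
              paste(nms[c(1, 1, 2)], nms[c(2, 3, 3)], sep = "&"),
              paste(nms, collapse = "&"))
  names(counts) <- labels
  tab <- table(region)
  counts[names(tab)[names(tab) %in% labels]] <-
    tab[names(tab)[names(tab) %in% labels]]
  list(region = stats::setNames(region, all_genes), counts = counts)
}

#' Derive the cross-grade malignancy signature by list intersection
#'
#' Intersects the thresholded up- and down-regulated gene lists of three
#' comparisons of aggressive tumor groups against non-recurrent benign
#' tumors. The signature is the triple intersection of the up-lists
#' (direction "up") together with the triple intersection of the down-lists
#' (direction "down"); all seven Venn regions are reported per direction. A
#' gene that appears up in one comparison and down in another is excluded
#' from the signature and recorded in the `conflicts` element.
#'
#' @param lists Named list of exactly three elements, each a
#'   `list(up =, down =)` pair as returned by [de_gene_list()]. Names label
#'   the comparisons (e.g. `"1M+R"`, `"2M+R"`, `"WHOIII"`).
#' @return A `Signature` object: list with `genes` (data.frame of `gene`,
#'   `direction`, `member_of`), `venn` (per-direction 7-region counts),
#'   `conflicts` (genes with inconsistent direction across comparisons).
#' @export
intersect_signature <- function(lists) {
  if (length(lists) != 3 || is.null(names(lists))) {
    stop("`lists` must be a named list of three (up, down) pairs",
         call. = FALSE)
  }
  ups <- lapply(lists, `[[`, "up")
  downs <- lapply(lists, `[[`, "down")
  conflicts <- intersect(unlist(ups), unlist(downs))
  up_core <- setdiff(Reduce(intersect, ups), conflicts)
  down_core <- setdiff(Reduce(intersect, downs), conflicts)
  venn_up <- venn_regions(ups)
  venn_down <- venn_regions(downs)
  member <- function(g, sets) {
    vapply(g, function(x) paste(names(sets)[vapply(sets, function(s)
      x %in% s, logical(1))], collapse = "&"), "")
  }
  genes <- data.frame(
    gene = c(up_core, down_core),
    direction = rep(c("up", "down"), c(length(up_core), length(down_core))),
    member_of = c(member(up_core, ups), member(down_core, downs)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(genes = genes,
                 venn = list(up = venn_up$counts, down = venn_down$counts),
                 conflicts = conflicts,
                 list_sizes = list(up = lengths(ups), down = lengths(downs))),
            class = "Signature")
}

#' @export
print.Signature <- function(x, ...) {
  n_up <- sum(x$genes$direction == "up")
  n_down <- sum(x$genes$direction == "down")
  cat(sprintf("Malignancy signature: %d gene(s) (%d up, %d down)\n",
              nrow(x$genes), n_up, n_down))
  if (length(x$conflicts) > 0) {
    cat(sprintf("  %d gene(s) excluded for direction conflicts\n",
                length(x$conflicts)))
  }
  invisible(x)
}

#' Select top candidate genes for validation
#'
#' Applies the two-stage candidate filter: a gene qualifies when (i) in the
#' grade III vs grade I comparison it reaches `p < p_main` with a fold change
#' above the 90th or below the 10th percentile of that comparison's
#' fold-change distribution (linear-interpolation quantiles), and (ii) it
#' passes `p < p_subgroup` with a two-sided fold change beyond `fc_subgroup`
#' in at least `min_subgroup_hits` of the clinico-pathological subgroup
#' comparisons. Literature-driven additions (e.g. AURKB) can be supplied via
#' `manual` and are flagged as such rather than filtered.
#'
#' @param whoIII_vs_I `DifferentialResult` for the grade III vs grade I
#'   comparison (needs >= 10 genes so the percentiles are defined).
#' @param subgroup_results Named list of `DifferentialResult` data.frames,
#'   one per subgroup comparison.
#' @param p_main P cutoff for the grade III vs I stage (default 0.01).
#' @param p_subgroup,fc_subgroup Cutoffs for the subgroup stage
#'   (defaults 0.01 and 1.25).
#' @param min_subgroup_hits Minimum qualifying subgroup comparisons
#'   (default 2).
#' @param manual Character vector of genes added by hand.
#' @return Data.frame with columns `gene` and `source`
#'   (`"filter"`/`"manual"`).
#' @export
select_candidates <- function(whoIII_vs_I, subgroup_results,
                              p_main = 0.01, p_subgroup = 0.01,
                              fc_subgroup = 1.25, min_subgroup_hits = 2,
                              manual = character(0)) {
  if (nrow(whoIII_vs_I) < 10) {
    stop("need at least 10 genes to define fold-change percentiles",
         call. = FALSE)
  }
  fc <- whoIII_vs_I$fold_change_linear
  hi <- stats::quantile(fc, 0.9, names = FALSE)  # type 7: linear interpolation
  lo <- stats::quantile(fc, 0.1, names = FALSE)
  stage1 <- whoIII_vs_I$gene[whoIII_vs_I$p_value < p_main &
                               (fc > hi | fc < lo)]
  hits <- table(unlist(lapply(subgroup_results, function(res) {
    l <- de_gene_list(res, p_subgroup, fc_subgroup)
    c(l$up, l$down)
  })))
  stage2 <- names(hits)[hits >= min_subgroup_hits]
  selected <- intersect(stage1, stage2)
  out <- data.frame(
    gene = c(selected, setdiff(manual, selected)),
    source = c(rep("filter", length(selected)),
               rep("manual", length(setdiff(manual, selected)))),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fc_percentiles") <- c(p10 = lo, p90 = hi)
  out
}
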