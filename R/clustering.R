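#' Principal component analysis of samples
#'
#' PCA over samples (observations) with genes as variables. Gene-wise
#' centering is applied; components are orthonormal and ordered by
#' decreasing explained variance.
#'
#' @param em Log2-scale `ExpressionMatrix` (ideally centered) with >= 2
#'   samples.
#' @return List with `scores` (samples x components), `explained` (fractions
#'   of variance, non-increasing, summing to at most 1) and the underlying
#'   `prcomp` fit.
#' @export
pca_samples <- function(em) {
  check_scale(em, "log2", "pca_samples")
  vals <- em$values
  if (ncol(vals) < 2) stop("need at least 2 samples", call. = FALSE)
  if (all(apply(vals, 1, stats::var) < .Machine$double.eps)) {
    stop("constant matrix: no variance to decompose", call. = FALSE)
  }
  fit <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, explained = expl, fit = fit)
}

#' Hierarchical clustering of samples on signature genes
#'
#' Agglomerative clustering of samples using, by default, one minus the
#' Pearson correlation across the signature genes as the distance and
#' average linkage — the common defaults for expression heatmaps. The
#' dendrogram is cut into `k` clusters.
#'
#' @param em Log2-scale `ExpressionMatrix`, typically restricted to
#'   signature genes (`em$values[sig_genes, ]`).
#' @param k Number of clusters (>= 2, at most the number of samples).
#' @param distance `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @param linkage Agglomeration rule passed to [stats::hclust()]
#'   (default `"average"`).
#' @return A `ClusterAssignment` list: `cluster` (named integer vector,
#'   sample -> 1..k), `hclust` (the merge tree), `k`.
#' @export
hierarchical_cluster <- function(em, k = 3, distance = c("correlation",
                                                         "euclidean"),
                                 linkage = "average") {
  stopifnot(inherits(em, "ExpressionMatrix"))
  distance <- match.arg(distance)
  n <- ncol(em$values)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  d <- if (distance == "correlation") {
    stats::as.dist(1 - stats::cor(em$values))
  } else {
    stats::dist(t(em$values))
  }
  tree <- stats::hclust(d, method = linkage)
  structure(list(cluster = stats::cutree(tree, k = k), hclust = tree, k = k),
            class = "ClusterAssignment")
}

#' Cluster composition by clinical category
#'
#' Tabulates, per cluster, how many samples fall in each WHO-grade x
#' subgroup category (e.g. `1NR`, `3R`). Samples missing from the annotation
#' are counted under `"unknown"`.
#'
#' @param assignment A `ClusterAssignment` from [hierarchical_cluster()].
#' @param ann A `SampleAnnotation` data.frame.
#' @return A contingency table, clusters x categories.
#' @export
cluster_composition <- function(assignment, ann) {
  stopifnot(inherits(assignment, "ClusterAssignment"))
  samples <- names(assignment$cluster)
  idx <- match(samples, ann$sample_id)
  grade_num <- c(I = "1", II = "2", III = "3")
  category <- ifelse(is.na(idx), "unknown",
                     paste0(grade_num[ann$who_grade[idx]],
                            ann$subgroup[idx]))
  table(cluster = assignment$cluster, category = category)
}
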