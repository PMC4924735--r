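#' Quantile-spline (qspline) inter-array normalization
#'
#' Removes array-to-array intensity distortions by mapping each array onto a
#' common reference pseudo-array through a monotone spline fitted at matched
#' quantile anchors. The reference quantile at each anchor is the geometric
#' mean of the arrays' quantiles, so the reference is a "typical" array on
#' the linear intensity scale. Each array's mapping interpolates
#' (array quantile -> reference quantile) pairs with a monotone cubic spline
#' (Hyman filtering), guaranteeing a non-decreasing transform over the
#' observed range; anchors include the distribution extremes so no
#' extrapolation is needed.
#'
#' @param em Linear-scale `ExpressionMatrix` with strictly positive values.
#' @param n_anchors Number of quantile anchors (default 14), spaced evenly
#'   in probability from 0 to 1.
#' @return A linear-scale `ExpressionMatrix` of the same dimensions, with an
#'   `"anchors"` attribute holding the per-array anchor quantiles and the
#'   reference quantiles.
#' @export
qspline_normalize <- function(em, n_anchors = 14) {
  check_scale(em, "linear", "qspline_normalize")
  vals <- em$values
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("qspline_normalize requires finite, strictly positive intensities",
         call. = FALSE)
  }
  if (ncol(vals) < 2) {
    warning("single array: qspline normalization is the identity")
    return(em)
  }
  probs <- seq(0, 1, length.out = max(4L, as.integer(n_anchors)))
  anchors <- apply(vals, 2, stats::quantile, probs = probs, names = FALSE)
  ref <- exp(rowMeans(log(anchors)))  # geometric mean across arrays
  out <- vals
  for (j in seq_len(ncol(vals))) {
    x <- anchors[, j]
    y <- ref
    keep <- !duplicated(x)
    x <- x[keep]
    y <- y[keep]
    if (length(x) < 2) next  # constant array: leave unchanged
    # collapse any residual ties in y to keep the spline monotone
    y <- cummax(y)
    f <- if (length(x) >= 4) {
      stats::splinefun(x, y, method = "hyman")
    } else {
      stats::approxfun(x, y, rule = 2)
    }
    out[, j] <- f(vals[, j])
  }
  res <- expression_matrix(out, scale = "linear",
                           probe_to_gene = em$probe_to_gene)
  attr(res, "anchors") <- list(probs = probs, array_quantiles = anchors,
                               reference = ref)
  res
}

#' Median probe-set summarization
#'
#' Collapses probe-level rows to one row per gene by taking, per sample, the
#' median across the gene's probes (the even-count median is the mean of the
#' middle pair). Probes with no gene mapping are dropped and counted.
#'
#' @param em An `ExpressionMatrix` at probe level.
#' @param probe_to_gene Named character vector, probe id -> gene symbol;
#'   defaults to the map stored on `em`.
#' @return An `ExpressionMatrix` with one row per gene (same scale), carrying
#'   a `"dropped_probes"` attribute with the number of unmapped probes.
#' @export
summarize_probes <- function(em, probe_to_gene = em$probe_to_gene) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(probe_to_gene)) {
    stop("no probe-to-gene mapping available", call. = FALSE)
  }
  probes <- rownames(em$values)
  gene <- unname(probe_to_gene[probes])
  dropped <- sum(is.na(gene))
  keep <- !is.na(gene)
  vals <- em$values[keep, , drop = FALSE]
  gene <- gene[keep]
  idx <- split(seq_len(nrow(vals)), gene)
  out <- matrix(NA_real_, length(idx), ncol(vals),
                dimnames = list(names(idx), colnames(vals)))
  for (g in seq_along(idx)) {
    rows <- idx[[g]]
    out[g, ] <- if (length(rows) == 1) vals[rows, ] else
      apply(vals[rows, , drop = FALSE], 2, stats::median)
  }
  res <- expression_matrix(out, scale = em$scale)
  attr(res, "dropped_probes") <- dropped
  res
}

#' Log2-transform a linear-scale matrix
#'
#' @param em A linear-scale `ExpressionMatrix` with positive values.
#' @return The log2-scale `ExpressionMatrix`.
#' @export
transform_log2 <- function(em) {
  check_scale(em, "linear", "transform_log2")
  bad <- which(em$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive value at feature '%s', sample '%s': log2 undefined",
                 rownames(em$values)[bad[1, 1]],
                 colnames(em$values)[bad[1, 2]]), call. = FALSE)
  }
  expression_matrix(log2(em$values), scale = "log2",
                    probe_to_gene = em$probe_to_gene)
}

#' Remove batch effects by per-gene linear model
#'
#' Fits, for every gene, `value ~ intercept + batch` by least squares on the
#' log2 scale (additive model) and subtracts the estimated batch terms. The
#' reference batch is the first label alphabetically; the removed batch
#' contribution is centered across samples before subtraction, so the
#' per-gene grand mean is preserved exactly. A batch with a single sample is
#' retained with a warning (estimable but noisy); a single batch overall
#' makes the operation the identity.
#'
#' @param em Log2-scale `ExpressionMatrix`.
#' @param batch Character or factor of batch labels, one per sample.
#' @return Corrected `ExpressionMatrix` with a `"batch_coefficients"`
#'   attribute (genes x non-reference batches).
#' @export
batch_correct <- function(em, batch) {
  check_scale(em, "log2", "batch_correct")
  vals <- em$values
  if (length(batch) != ncol(vals)) {
    stop("`batch` must have one label per sample", call. = FALSE)
  }
  batch <- factor(as.character(batch), levels = sort(unique(as.character(batch))))
  if (nlevels(batch) < 2) return(em)
  sizes <- table(batch)
  if (any(sizes < 2)) {
    warning("batch(es) with a single sample: ",
            paste(names(sizes)[sizes < 2], collapse = ", "),
            "; estimates will be noisy")
  }
  X <- stats::model.matrix(~batch)
  fit <- stats::lm.fit(X, t(vals))
  coefs <- fit$coefficients
  batch_cols <- seq(2, ncol(X))
  contrib <- X[, batch_cols, drop = FALSE] %*%
    coefs[batch_cols, , drop = FALSE]        # samples x genes
  contrib <- t(contrib)                      # genes x samples
  contrib <- contrib - rowMeans(contrib)     # preserve per-gene grand mean
  res <- expression_matrix(vals - contrib, scale = "log2",
                           probe_to_gene = em$probe_to_gene)
  bc <- t(coefs[batch_cols, , drop = FALSE])
  colnames(bc) <- levels(batch)[-1]
  attr(res, "batch_coefficients") <- bc
  res
}

#' Median-center each array
#'
#' Subtracts the per-array median so every array's median becomes 0. Linear
#' input is log2-transformed first (an error names the offending cell if a
#' non-positive value blocks the log step).
#'
#' @param em An `ExpressionMatrix` (linear or log2).
#' @return A log2-scale, per-array median-centered `ExpressionMatrix`.
#' @export
median_center_log2 <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale == "linear") em <- transform_log2(em)
  meds <- apply(em$values, 2, stats::median)
  expression_matrix(sweep(em$values, 2, meds), scale = "log2",
                    probe_to_gene = em$probe_to_gene)
}

#' Full normalization chain
#'
#' Runs the complete preprocessing pipeline on raw linear intensities:
#' qspline inter-array normalization, median probe-set summarization (when a
#' probe-to-gene map is present), log2 transformation, per-gene linear-model
#' batch correction, and per-array median centering. Batch correction is
#' applied on the log2 scale, where a linear model means "additive", and
#' median centering comes last so the delivered matrix is centered log2 data.
#'
#' @param em Raw linear-scale `ExpressionMatrix`.
#' @param batch Optional batch labels (one per sample); `NULL` skips batch
#'   correction.
#' @param n_anchors Anchor count for [qspline_normalize()].
#' @param skip_qspline Set `TRUE` for input that is already inter-array
#'   normalized.
#' @return A list with `matrix` (the centered log2 `ExpressionMatrix`) and
#'   `report` (per-array pre/post quartile summaries, dropped-probe count,
#'   batch coefficients).
#' @export
normalize_pipeline <- function(em, batch = NULL, n_anchors = 14,
                               skip_qspline = FALSE) {
  check_scale(em, "linear", "normalize_pipeline")
  five_num <- function(m) t(apply(m, 2, stats::quantile,
                                  probs = c(0, .25, .5, .75, 1)))
  pre <- five_num(em$values)
  step <- if (skip_qspline) em else qspline_normalize(em, n_anchors)
  dropped <- 0L
  if (!is.null(step$probe_to_gene)) {
    step <- summarize_probes(step)
    dropped <- attr(step, "dropped_probes")
  }
  step <- transform_log2(step)
  bc <- NULL
  if (!is.null(batch)) {
    step <- batch_correct(step, batch)
    bc <- attr(step, "batch_coefficients")
  }
  step <- median_center_log2(step)
  list(matrix = step,
       report = list(pre_quantiles = pre, post_quantiles = five_num(step$values),
                     dropped_probes = dropped, batch_coefficients = bc))
}
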