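#' Expression matrix container
#'
#' A light S3 container for a features-by-samples intensity matrix. Rows are
#' probes or genes (duplicate row identifiers are allowed, since several
#' probes may interrogate the same transcript), columns are samples
#' (duplicates are rejected). The `scale` flag records whether values are raw
#' linear intensities or log2-transformed; operations that only make sense on
#' one scale check it and refuse the other.
#'
#' @param values Numeric matrix with rownames (feature ids) and colnames
#'   (sample ids). Orientation is fixed: rows are features, columns samples.
#' @param scale Either `"linear"` (raw intensities) or `"log2"`.
#' @param probe_to_gene Optional named character vector mapping probe ids
#'   (names) to gene symbols (values), used by [summarize_probes()].
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `scale` and `probe_to_gene`.
#' @examples
#' m <- matrix(2^rnorm(6, 8), 3, 2,
#'             dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
#' em <- expression_matrix(m, scale = "linear")
#' dim(em)
#' @export
expression_matrix <- function(values, scale = c("log2", "linear"),
                              probe_to_gene = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (features) and colnames (samples)",
         call. = FALSE)
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup) > 0) {
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(probe_to_gene)) {
    if (is.null(names(probe_to_gene)) || !is.character(probe_to_gene)) {
      stop("`probe_to_gene` must be a named character vector (probe -> gene)",
           call. = FALSE)
    }
  }
  structure(list(values = values, scale = scale,
                 probe_to_gene = probe_to_gene),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d feature(s) x %d sample(s), %s scale\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$probe_to_gene)) {
    cat(sprintf("  probe->gene map: %d probe(s), %d gene(s)\n",
                length(x$probe_to_gene), length(unique(x$probe_to_gene))))
  }
  invisible(x)
}

#' Extract the values of an ExpressionMatrix
#'
#' @param x An `ExpressionMatrix`.
#' @return The numeric matrix of intensities.
#' @export
em_values <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x$values
}

# internal: insist on a given scale before a scale-sensitive operation
check_scale <- function(x, required, op) {
  if (!inherits(x, "ExpressionMatrix")) {
    stop(op, " expects an ExpressionMatrix", call. = FALSE)
  }
  if (x$scale != required) {
    stop(sprintf("%s requires a %s-scale matrix (got %s)", op, required,
                 x$scale), call. = FALSE)
  }
  invisible(x)
}
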