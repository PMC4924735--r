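# small in-code fixtures shared across test files

toy_matrix <- function(nr = 3, nc = 2, seed = 42, scale = "log2") {
  set.seed(seed)
  m <- matrix(round(rnorm(nr * nc, 8, 1), 4), nr, nc,
              dimnames = list(sprintf("g%d", seq_len(nr)),
                              sprintf("s%d", seq_len(nc))))
  if (scale == "linear") m <- 2^m
  expression_matrix(m, scale = scale)
}

# annotation row with sensible defaults, overridable per field
ann_row <- function(sample_id = "s1", who_grade = "I", subgroup = "NR",
                    simpson = 1, followup_months = 40, pfs_months = 40,
                    progression_event = FALSE, ...) {
  data.frame(sample_id = sample_id, who_grade = who_grade,
             subgroup = subgroup, simpson = simpson,
             followup_months = followup_months, pfs_months = pfs_months,
             progression_event = progression_event, ...,
             stringsAsFactors = FALSE)
}

# two-group log2 matrix with per-gene values laid out explicitly
two_group_matrix <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  m <- cbind(a, b)
  dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))),
                      c(sprintf("a%d", seq_len(ncol(a))),
                        sprintf("b%d", seq_len(ncol(b)))))
  list(em = expression_matrix(m, scale = "log2"),
       group_a = colnames(m)[seq_len(ncol(a))],
       group_b = colnames(m)[ncol(a) + seq_len(ncol(b))])
}

# exhaustive two-sided Mann-Whitney p by enumerating all group assignments
mw_exact_enum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_stat <- function(x, y) {
    sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  obs <- u_stat(a, b)
  splits <- utils::combn(n, na)
  us <- apply(splits, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p <- 2 * min(mean(us <= obs), mean(us >= obs))
  min(1, p)
}
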