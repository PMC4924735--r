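#' Filter samples into the survival-eligible cohort
#'
#' Applies the study inclusion rules for progression-free survival (PFS)
#' analysis: only primary, treatment-naive tumors after complete resection
#' (Simpson grade 1-3) are eligible, and event-free records must carry at
#' least `min_followup` months of follow-up (default 36) so that "no
#' recurrence" is meaningful. Exclusion reasons are recorded per dropped
#' sample.
#'
#' @param ann A `SampleAnnotation` data.frame.
#' @param min_followup Minimum follow-up in months for censored records.
#' @return The eligible subset, with an `"exclusions"` attribute
#'   (data.frame of `sample_id`, `reason`).
#' @export
filter_survival_cohort <- function(ann, min_followup = 36) {
  if (nrow(ann) == 0) {
    out <- ann
    attr(out, "exclusions") <- data.frame(sample_id = character(0),
                                          reason = character(0))
    return(out)
  }
  reason <- rep(NA_character_, nrow(ann))
  not_primary <- !is.na(ann$is_primary) & !ann$is_primary
  reason[not_primary] <- "recurrent tumor (not index surgery)"
  pretreated <- !is.na(ann$treatment_naive) & !ann$treatment_naive
  reason[is.na(reason) & pretreated] <- "prior radio-/chemotherapy"
  incomplete <- is.na(ann$simpson) | ann$simpson > 3
  reason[is.na(reason) & incomplete] <- "incomplete resection (Simpson > 3 or unknown)"
  event <- !is.na(ann$progression_event) & ann$progression_event
  short_fu <- !event & (is.na(ann$followup_months) |
                          ann$followup_months < min_followup)
  reason[is.na(reason) & short_fu] <-
    sprintf("event-free with follow-up < %d months", min_followup)
  keep <- is.na(reason)
  out <- ann[keep, , drop = FALSE]
  attr(out, "exclusions") <- data.frame(sample_id = ann$sample_id[!keep],
                                        reason = reason[!keep],
                                        stringsAsFactors = FALSE)
  out
}

#' Dichotomize a biomarker into high/low groups
#'
#' Median rule: high when the value strictly exceeds the cohort median.
#' Upper-quartile rule: high when it strictly exceeds the 75th percentile
#' (linear-interpolation quantiles). Values exactly at the cut go to "low".
#'
#' @param values Named (or plain) numeric vector, one value per sample.
#' @param rule `"median"` or `"upper_quartile"`.
#' @return Factor with levels `low`, `high` and a `"cut"` attribute.
#' @export
dichotomize <- function(values, rule = c("median", "upper_quartile")) {
  rule <- match.arg(rule)
  if (length(unique(values)) == 1) {
    stop("all values identical: no split possible", call. = FALSE)
  }
  cut <- if (rule == "median") stats::median(values) else
    stats::quantile(values, 0.75, names = FALSE)
  lab <- factor(ifelse(values > cut, "high", "low"),
                levels = c("low", "high"))
  names(lab) <- names(values)
  attr(lab, "cut") <- cut
  lab
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Non-negative event/censoring times (months).
#' @param event Logical (or 0/1): `TRUE` when progression was observed.
#' @return Data.frame with `time`, `n_risk`, `n_event`, `survival`, plus the
#'   underlying [survival::survfit] object as attribute `"fit"`. With no
#'   events the curve is flat at 1.
#' @export
km_estimate <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  attr(out, "fit") <- fit
  out
}

#' Two-or-more-group log-rank test
#'
#' @param time,event Survival outcome as in [km_estimate()].
#' @param group Group labels (each group must be non-empty).
#' @return List with `chisq`, `df`, `p_value` and the
#'   [survival::survdiff] fit.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  df <- length(sd$n) - 1
  list(chisq = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE), fit = sd)
}

#' Cox proportional-hazards fit with tidy output
#'
#' Fits `Surv(time, event) ~ covariates` by partial likelihood with Efron
#' tie handling. In `"univariate"` mode each covariate is fit in its own
#' model (the usual screening step); `"multivariate"` fits them jointly.
#' Categorical covariates are expanded against their first (reference)
#' level, so a factor WHO grade yields "II vs I" and "III vs I" terms.
#' Per-term p-values are Wald tests; each model also carries a score
#' (log-rank) and likelihood-ratio p-value, which for a single covariate is
#' the log-rank-type p quoted alongside hazard ratios.
#'
#' @param data Data.frame containing `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param model `"univariate"` (default) or `"multivariate"`.
#' @param time_col,event_col Names of the outcome columns.
#' @return A `CoxFit` data.frame: `model`, `term`, `hr`, `ci_lower`,
#'   `ci_upper`, `p_wald`, `p_score`, `p_lr`, `loglik`, `n`, `n_event`.
#' @export
cox_fit <- function(data, covariates, model = c("univariate", "multivariate"),
                    time_col = "time", event_col = "event") {
  model <- match.arg(model)
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) stop("covariate not found: ", cv, call. = FALSE)
    if (length(unique(v[!is.na(v)])) < 2) {
      stop("constant covariate: ", cv, call. = FALSE)
    }
  }
  n_event <- sum(data[[event_col]])
  if (n_event < 5 * length(covariates) && model == "multivariate") {
    warning(sprintf("only %d events for %d covariate(s); estimates may be unstable",
                    n_event, length(covariates)))
  }
  fit_one <- function(covs, label) {
    fml <- stats::as.formula(paste0(
      "survival::Surv(", time_col, ", as.integer(", event_col, ")) ~ ",
      paste(covs, collapse = " + ")))
    fit <- survival::coxph(fml, data = data, ties = "efron")
    sm <- summary(fit)
    co <- sm$coefficients
    ci <- sm$conf.int
    data.frame(model = label, term = rownames(co),
               hr = unname(co[, "exp(coef)"]),
               ci_lower = unname(ci[, "lower .95"]),
               ci_upper = unname(ci[, "upper .95"]),
               p_wald = unname(co[, "Pr(>|z|)"]),
               p_score = unname(sm$sctest["pvalue"]),
               p_lr = unname(sm$logtest["pvalue"]),
               loglik = fit$loglik[2], n = sm$n, n_event = sm$nevent,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- if (model == "univariate") {
    do.call(rbind, lapply(covariates, function(cv) fit_one(cv, cv)))
  } else {
    fit_one(covariates, "multivariate")
  }
  class(res) <- c("CoxFit", "data.frame")
  res
}

#' Select covariates for the multivariate model from univariate screening
#'
#' Clinical confounders enter the multivariate model when their univariate
#' p-value falls below `threshold` (default 0.05). Candidate genes follow a
#' stricter entry rule: only genes with a multiplicity-unadjusted univariate
#' p below `gene_threshold` (default 0.001) are carried forward.
#'
#' @param univariate A `CoxFit` data.frame from univariate [cox_fit()].
#' @param threshold Significance threshold for clinical covariates.
#' @param gene_covariates Names of covariates that are gene expressions.
#' @param gene_threshold Entry threshold for gene covariates.
#' @param p_column Which p-value governs selection (default `"p_score"`,
#'   the log-rank-type model p).
#' @return Character vector of selected covariate (model) names.
#' @export
select_multivariate_covariates <- function(univariate, threshold = 0.05,
                                           gene_covariates = character(0),
                                           gene_threshold = 0.001,
                                           p_column = "p_score") {
  per_model <- univariate[!duplicated(univariate$model), ]
  is_gene <- per_model$model %in% gene_covariates
  keep <- (!is_gene & per_model[[p_column]] < threshold) |
    (is_gene & per_model[[p_column]] < gene_threshold)
  per_model$model[keep]
}

#' Four-level grouping from combined PTTG1-like and LEPR-like expression
#'
#' Dichotomizes the hazard-increasing marker by its upper quartile and the
#' hazard-decreasing marker by its median, and crosses the two labels into
#' four groups. When survival data are supplied, the group-wise log-rank
#' test and median PFS per group are computed as well.
#'
#' @param pttg1_values,lepr_values Numeric vectors over the same samples
#'   (names are aligned when present).
#' @param time,event Optional survival outcome for the same samples.
#' @return List with `group` (factor with levels
#'   `"PTTG1-low/LEPR-high"`, `"PTTG1-low/LEPR-low"`,
#'   `"PTTG1-high/LEPR-high"`, `"PTTG1-high/LEPR-low"`), `sizes`, `cuts`,
#'   and (when survival data are given) `logrank` and `median_pfs`.
#' @export
combined_gene_groups <- function(pttg1_values, lepr_values,
                                 time = NULL, event = NULL) {
  if (length(pttg1_values) != length(lepr_values)) {
    stop("marker vectors must cover the same samples", call. = FALSE)
  }
  if (!is.null(names(pttg1_values)) && !is.null(names(lepr_values))) {
    lepr_values <- lepr_values[names(pttg1_values)]
  }
  p_lab <- dichotomize(pttg1_values, "upper_quartile")
  l_lab <- dichotomize(lepr_values, "median")
  group <- factor(paste0("PTTG1-", as.character(p_lab),
                         "/LEPR-", as.character(l_lab)),
                  levels = c("PTTG1-low/LEPR-high", "PTTG1-low/LEPR-low",
                             "PTTG1-high/LEPR-high", "PTTG1-high/LEPR-low"))
  names(group) <- names(pttg1_values)
  out <- list(group = group, sizes = table(group),
              cuts = c(pttg1 = attr(p_lab, "cut"), lepr = attr(l_lab, "cut")))
  if (!is.null(time)) {
    present <- levels(group)[table(group) > 0]
    out$logrank <- logrank_test(time, event, factor(group,
                                                    levels = present))
    fit <- survival::survfit(
      survival::Surv(time, as.integer(event)) ~ group)
    med <- summary(fit)$table
    out$median_pfs <- stats::setNames(med[, "median"],
                                      sub("^group=", "", rownames(med)))
  }
  out
}
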