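#' Simulation configuration for a synthetic meningioma cohort
#'
#' Defaults emulate the structure of a 62-sample microarray discovery
#' cohort: three WHO grades (20/14/28 samples) split into
#' clinico-pathological subgroups, 5000 genes of which 208 are planted as
#' shared up-regulated and 124 as shared down-regulated in all aggressive
#' subgroups (recurrent, malignantly progressing, or grade III), additive
#' per-batch offsets, per-array intensity scaling, an exponential
#' proportional-hazards progression model tied to two planted biomarker
#' genes (one hazard-increasing "PTTG1-like", one hazard-decreasing
#' "LEPR-like"), 13 matched primary/recurrent pairs (6 with stable and 7
#' with increasing WHO grade), Cq triplicates and staining fractions.
#'
#' @param cells Named integer vector of samples per WHO-grade x subgroup
#'   cell (names like `"1NR"`, `"3R"`, `"3NA"`).
#' @param n_genes Total number of genes.
#' @param n_up,n_down Numbers of planted shared up-/down-regulated genes.
#' @param delta_log2 Planted log2 effect size in aggressive samples.
#' @param resid_sd Residual (biological + technical) SD on the log2 scale.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 intensity
#'   distribution.
#' @param n_batches Number of processing batches.
#' @param batch_sd SD of per-gene additive batch offsets (log2 scale).
#' @param array_scale_sd SD of per-array log2 intensity scaling (what
#'   inter-array normalization removes).
#' @param extra_probe_frac Fraction of genes interrogated by a second probe.
#' @param effect_mode `"shared"` (identical effect in all aggressive
#'   subgroups, the default) or `"gradient"` (effect scaled up with WHO
#'   grade, producing a spectrum along the first principal component).
#' @param baseline_rate Baseline monthly progression hazard.
#' @param log_hr_pttg1,log_hr_lepr Log hazard ratios per SD of the two
#'   planted biomarker genes (positive and negative, respectively).
#' @param censor_rate Rate of the independent exponential censoring process.
#' @param followup_horizon Administrative censoring horizon (months).
#' @param n_pairs_stable,n_pairs_increasing Matched pairs with stable /
#'   increasing WHO grade at recurrence.
#' @param pair_shift_log2 Mean log2 recurrence shift of risk genes in the
#'   increasing-grade pairs (protective genes shift the opposite way).
#' @param pair_sd SD of per-pair log2 changes.
#' @param cq_noise_sd SD of Cq measurement noise (cycles).
#' @param hk_cq Named vector of constant housekeeping Cq values.
#' @param seed Integer seed: identical seeds give identical cohorts.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(cells = c("1NR" = 12, "1R" = 4, "1M" = 4,
                                        "2NR" = 6, "2R" = 4, "2M" = 4,
                                        "3NR" = 6, "3R" = 18, "3NA" = 4),
                              n_genes = 5000, n_up = 208, n_down = 124,
                              delta_log2 = 1.0, resid_sd = 0.5,
                              baseline_mean = 8, baseline_sd = 1,
                              n_batches = 2, batch_sd = 0.3,
                              array_scale_sd = 0.2, extra_probe_frac = 0.1,
                              effect_mode = c("shared", "gradient"),
                              baseline_rate = 0.01,
                              log_hr_pttg1 = log(2), log_hr_lepr = -log(2),
                              censor_rate = 0.005, followup_horizon = 120,
                              n_pairs_stable = 6, n_pairs_increasing = 7,
                              pair_shift_log2 = 1.5, pair_sd = 0.8,
                              cq_noise_sd = 0.2,
                              hk_cq = c(ACTB = 20, GNB1 = 22),
                              seed = 1) {
  effect_mode <- match.arg(effect_mode)
  cfg <- list(cells = cells, n_genes = n_genes, n_up = n_up, n_down = n_down,
              delta_log2 = delta_log2, resid_sd = resid_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              n_batches = n_batches, batch_sd = batch_sd,
              array_scale_sd = array_scale_sd,
              extra_probe_frac = extra_probe_frac, effect_mode = effect_mode,
              baseline_rate = baseline_rate, log_hr_pttg1 = log_hr_pttg1,
              log_hr_lepr = log_hr_lepr, censor_rate = censor_rate,
              followup_horizon = followup_horizon,
              n_pairs_stable = n_pairs_stable,
              n_pairs_increasing = n_pairs_increasing,
              pair_shift_log2 = pair_shift_log2, pair_sd = pair_sd,
              cq_noise_sd = cq_noise_sd, hk_cq = hk_cq, seed = seed)
  counts <- c(cfg$n_genes, cfg$n_up, cfg$n_down, cfg$n_batches,
              cfg$n_pairs_stable, cfg$n_pairs_increasing)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (cfg$n_up + cfg$n_down > cfg$n_genes) {
    stop("more planted genes than genes", call. = FALSE)
  }
  sds <- c(cfg$resid_sd, cfg$batch_sd, cfg$array_scale_sd, cfg$cq_noise_sd,
           cfg$pair_sd)
  if (any(sds < 0)) stop("standard deviations must be non-negative",
                         call. = FALSE)
  if (cfg$n_up < 1 || cfg$n_down < 1) {
    stop("need at least one planted gene per direction (the biomarkers)",
         call. = FALSE)
  }
  bad <- grepl("^[123](NR|R|M|NA)$", names(cells))
  if (!all(bad)) {
    stop("cell names must look like '1NR', '2M', '3NA', ...", call. = FALSE)
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Generate a synthetic meningioma cohort
#'
#' Produces raw probe-level linear intensities (per-array scaling and batch
#' offsets included, so the full normalization chain is exercised), a
#' validated sample annotation with progression-free survival drawn from an
#' exponential proportional-hazards model on the two planted biomarker
#' genes, a matched-pair expression table, and truth tables listing the
#' planted differentially expressed genes and hazard parameters.
#'
#' @param config A `SimulationConfig` (default [simulation_config()]).
#' @return List with `expression` (linear-scale probe-level
#'   `ExpressionMatrix` with probe-to-gene map), `annotation`
#'   (`SampleAnnotation`), `pairs` (list `values`, `progression`), and
#'   `truth` (planted gene ids, biomarker ids, log hazard ratios, noise-free
#'   log2 signal matrix, batch offsets).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  cells <- config$cells
  n <- sum(cells)
  cell_of <- rep(names(cells), cells)
  who <- c("1" = "I", "2" = "II", "3" = "III")[substr(cell_of, 1, 1)]
  subgroup <- substring(cell_of, 2)
  sample_id <- sprintf("S%03d", seq_len(n))
  aggressive <- who == "III" | subgroup %in% c("R", "M")

  genes <- sprintf("G%04d", seq_len(config$n_genes))
  up_genes <- genes[seq_len(config$n_up)]
  down_genes <- genes[config$n_up + seq_len(config$n_down)]
  pttg1_like <- up_genes[1]
  lepr_like <- down_genes[1]

  baseline <- stats::rnorm(config$n_genes, config$baseline_mean,
                           config$baseline_sd)
  names(baseline) <- genes
  effect_scale <- if (config$effect_mode == "shared") {
    as.numeric(aggressive)
  } else {
    as.numeric(aggressive) * c(I = 0.5, II = 0.75, III = 1)[who]
  }
  effect <- matrix(0, config$n_genes, n, dimnames = list(genes, sample_id))
  effect[up_genes, ] <- rep(config$delta_log2 * effect_scale,
                            each = length(up_genes))
  effect[down_genes, ] <- rep(-config$delta_log2 * effect_scale,
                              each = length(down_genes))
  signal <- baseline + effect  # noise-free log2 signal, genes x samples

  batch <- sample(rep_len(sprintf("b%d", seq_len(config$n_batches)), n))
  batch_offsets <- matrix(stats::rnorm(config$n_genes * config$n_batches,
                                       0, config$batch_sd),
                          config$n_genes, config$n_batches,
                          dimnames = list(genes,
                                          sprintf("b%d",
                                                  seq_len(config$n_batches))))
  array_scale <- stats::rnorm(n, 0, config$array_scale_sd)

  n_extra <- round(config$extra_probe_frac * config$n_genes)
  extra_genes <- if (n_extra > 0) sample(genes, n_extra) else character(0)
  probe_gene <- c(genes, extra_genes)
  probe_id <- c(paste0(probe_gene[seq_along(genes)], "_p1"),
                if (n_extra > 0) paste0(extra_genes, "_p2"))
  probe_to_gene <- stats::setNames(probe_gene, probe_id)

  log2_probe <- signal[probe_gene, , drop = FALSE] +
    batch_offsets[probe_gene, batch] +
    matrix(stats::rnorm(length(probe_gene) * n, 0, config$resid_sd),
           length(probe_gene), n)
  raw <- 2^sweep(log2_probe, 2, array_scale, "+")
  dimnames(raw) <- list(probe_id, sample_id)
  em <- expression_matrix(raw, scale = "linear",
                          probe_to_gene = probe_to_gene)

  # progression hazard driven by the standardized biomarker signal; a
  # constant signal (delta_log2 = 0) carries no prognostic information
  safe_z <- function(v) {
    s <- stats::sd(v)
    if (s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
  }
  z_p <- safe_z(signal[pttg1_like, ])
  z_l <- safe_z(signal[lepr_like, ])
  hazard <- config$baseline_rate *
    exp(config$log_hr_pttg1 * z_p + config$log_hr_lepr * z_l)
  t_event <- stats::rexp(n, hazard)
  t_censor <- pmin(stats::rexp(n, config$censor_rate),
                   config$followup_horizon)
  pfs <- pmin(t_event, t_censor)
  event <- t_event <= t_censor
  followup <- ifelse(event, pfs + stats::rexp(n, 0.05), pfs)
  followup <- pmin(followup, config$followup_horizon * 1.5)

  ann <- data.frame(
    sample_id = sample_id,
    patient_id = sprintf("P%03d", seq_len(n)),
    who_grade = unname(who), subgroup = subgroup,
    simpson = ifelse(subgroup == "NA", 4L, sample(1:3, n, replace = TRUE,
                                                  prob = c(.55, .2, .25))),
    followup_months = round(followup, 1), pfs_months = round(pfs, 1),
    progression_event = event,
    gender = sample(c("male", "female"), n, replace = TRUE,
                    prob = c(.39, .61)),
    age_years = round(pmin(pmax(stats::rnorm(n, 56, 13), 18), 83), 1),
    treatment_naive = stats::runif(n) > 0.15,
    is_primary = TRUE,
    batch = batch, center = sample(c("HD", "BN"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  ann <- validate_annotation(ann)

  pairs <- generate_pairs(config, up_genes, down_genes)

  list(expression = em, annotation = ann, pairs = pairs,
       truth = list(planted_up = up_genes, planted_down = down_genes,
                    pttg1_like = pttg1_like, lepr_like = lepr_like,
                    log_hr = c(pttg1 = config$log_hr_pttg1,
                               lepr = config$log_hr_lepr),
                    signal = signal, batch_offsets = batch_offsets,
                    aggressive = stats::setNames(aggressive, sample_id)))
}

# internal: matched primary/recurrent pairs over a small candidate panel
generate_pairs <- function(config, up_genes, down_genes) {
  n_pairs <- config$n_pairs_stable + config$n_pairs_increasing
  if (n_pairs == 0) {
    return(list(values = NULL, progression = NULL))
  }
  risk <- up_genes[seq_len(min(5, length(up_genes)))]
  protective <- down_genes[seq_len(min(2, length(down_genes)))]
  panel <- c(risk, protective)
  pid <- sprintf("MP%02d", seq_len(n_pairs))
  progression <- stats::setNames(
    rep(c("stable_who", "increasing_who"),
        c(config$n_pairs_stable, config$n_pairs_increasing)), pid)
  rows <- list()
  for (i in seq_len(n_pairs)) {
    for (g in panel) {
      primary <- 2^stats::rnorm(1, 0, config$pair_sd)
      shift_mean <- if (progression[i] == "increasing_who") {
        if (g %in% risk) config$pair_shift_log2 else -config$pair_shift_log2
      } else 0
      recurrent <- primary * 2^stats::rnorm(1, shift_mean, config$pair_sd)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid[i], timepoint = c(1L, 2L), gene = g,
        value = c(primary, recurrent), stringsAsFactors = FALSE)
    }
  }
  list(values = do.call(rbind, rows), progression = progression)
}

#' Generate a synthetic qPCR Cq table
#'
#' Emulates relative quantification against two constant housekeeping
#' genes: for each target gene the true relative quantity is the sample's
#' mean-centered noise-free log2 signal, and
#' `Cq = mean(housekeeping Cq) - log2(true relative value) + noise`, in
#' triplicate. With zero noise, [relative_expression()] inverts the
#' construction exactly.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param genes Target genes (default: the two planted biomarkers).
#' @param config The `SimulationConfig` used for the cohort.
#' @return A `QpcrTable` with a `"truth"` attribute holding the true
#'   relative values (genes x samples).
#' @export
generate_qpcr <- function(cohort, genes = NULL,
                          config = simulation_config()) {
  if (is.null(genes)) {
    genes <- c(cohort$truth$pttg1_like, cohort$truth$lepr_like)
  }
  signal <- cohort$truth$signal[genes, , drop = FALSE]
  rel_log2 <- signal - rowMeans(signal)
  ref <- mean(config$hk_cq)
  samples <- colnames(signal)
  rows <- list()
  for (s in samples) {
    for (hk in names(config$hk_cq)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, gene = hk, replicate = 1:3,
        cq = rep(unname(config$hk_cq[hk]), 3), stringsAsFactors = FALSE)
    }
    for (g in genes) {
      cq <- ref - rel_log2[g, s] +
        stats::rnorm(3, 0, config$cq_noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, gene = g, replicate = 1:3, cq = cq,
        stringsAsFactors = FALSE)
    }
  }
  tbl <- qpcr_table(do.call(rbind, rows),
                    housekeeping = names(config$hk_cq))
  attr(tbl, "truth") <- 2^rel_log2
  tbl
}

#' Generate a synthetic IHC staining table
#'
#' Staining reflects the planted aggressiveness class: aggressive tumors
#' show more scattered PTTG1-positive cells (hot-spot Poisson counts with a
#' higher mean) and weaker LEPR staining (intensity fractions shifted from
#' strong toward weak), so the combined score separates the classes by
#' construction.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param config The `SimulationConfig` used for the cohort.
#' @param n_fields High-power fields counted per sample.
#' @return An `IhcTable` for the cohort's samples.
#' @export
generate_ihc <- function(cohort, config = simulation_config(),
                         n_fields = 5) {
  aggressive <- cohort$truth$aggressive
  n <- length(aggressive)
  draw_frac <- function(mean_vec) {
    f <- pmax(stats::rnorm(3, mean_vec, 5), 0)
    if (sum(f) > 95) f <- f * 95 / sum(f)
    round(f, 1)
  }
  rows <- lapply(seq_len(n), function(i) {
    means <- if (aggressive[i]) c(40, 15, 5) else c(20, 30, 30)
    f <- draw_frac(means)
    lambda <- if (aggressive[i]) 25 else 3
    data.frame(sample_id = names(aggressive)[i],
               pct_weak = f[1], pct_moderate = f[2], pct_strong = f[3],
               pttg1_count = max(stats::rpois(n_fields, lambda)),
               stringsAsFactors = FALSE)
  })
  ihc_table(do.call(rbind, rows))
}

#' Simulate a proportional-hazards cohort with one binary covariate
#'
#' Event times are exponential with hazard `baseline_rate * hr^x` for a
#' balanced binary covariate `x`; independent exponential censoring is
#' calibrated so the expected censoring fraction matches `censor_frac`
#' (administrative horizon aside). Used for parameter-recovery and
#' confidence-interval coverage checks of the Cox machinery.
#'
#' @param n Number of subjects.
#' @param hr True hazard ratio of the covariate.
#' @param baseline_rate Baseline hazard (events per month).
#' @param censor_frac Target expected censoring fraction.
#' @param seed Optional integer seed.
#' @return Data.frame with `time`, `event`, `x`.
#' @export
generate_ph_cohort <- function(n, hr = 2, baseline_rate = 0.05,
                               censor_frac = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rep_len(c(0, 1), n)
  rate <- baseline_rate * hr^x
  t_event <- stats::rexp(n, rate)
  if (censor_frac > 0) {
    f <- function(rc) {
      mean(rc / (rc + baseline_rate * hr^c(0, 1))) - censor_frac
    }
    rc <- stats::uniroot(f, c(1e-8, 1e4 * baseline_rate))$root
    t_censor <- stats::rexp(n, rc)
  } else {
    t_censor <- rep(Inf, n)
  }
  data.frame(time = pmin(t_event, t_censor),
             event = t_event <= t_censor, x = x)
}
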