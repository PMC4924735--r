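# meningsig

Transcriptomic aggressiveness signatures and prognostic biomarkers in
meningioma.

Most meningiomas are benign (WHO grade I) and cured by surgery, but grade
II/III tumors — and a subset of histologically benign ones — recur, some
progressing to a higher grade. `meningsig` implements, as a tested and
reusable R pipeline, the analysis workflow used to characterize such
clinically aggressive tumors from bulk expression data: tumors are
labelled by WHO grade and by a *clinico-pathological subgroup* describing
their future behavior (NR = no recurrence within ≥ 36 months, R =
recurrence at the same grade, M = malignant progression, NA = no usable
follow-up), and genes whose expression separates aggressive tumors
(recurrent, progressing, or grade III) from non-recurrent grade I tumors
are identified, intersected into a directional malignancy signature,
validated by qPCR and immunohistochemistry statistics, and tested as
prognostic biomarkers for progression-free survival (PFS).

The package is aimed at analysts reproducing or extending this workflow on
their own expression cohorts, and at methodologists who want each stage —
normalization, permutation FDR, intersection signatures, survival
dichotomization — as an independently testable unit.

## What it computes

* **Preprocessing** (`normalize_pipeline`): qspline inter-array
  normalization (monotone splines through matched quantile anchors against
  a geometric-mean reference pseudo-array), median probe-set
  summarization, log2 transform, per-gene linear-model batch correction,
  per-array median centering.
* **Differential expression** (`t_test_de`, `permutation_fdr`): per-gene
  pooled t-tests with linear fold changes `FC = 2^(x̄_A − x̄_B)`; the FDR of
  a list thresholded at (p, FC) is estimated as
  `median(null pass counts) / observed pass count` over label
  permutations.
* **Signature** (`de_gene_list`, `intersect_signature`,
  `select_candidates`): triple intersection of up- and down-lists of the
  1M+R, 2M+R and WHO III vs 1NR comparisons at `p < 0.01` (grade III:
  `p < 0.001`) and `FC > 1.25` two-sided; candidate genes additionally
  need a fold change beyond the 90th/10th percentile of the grade III vs I
  comparison and hits in ≥ 2 subgroup comparisons.
* **Validation** (`qpcr_relative_expression`, `mann_whitney_compare`,
  `pair_changes`, `h_score`, `combined_ihc_score`): ΔCq relative
  quantification against the mean Cq of ACTB and GNB1; Mann–Whitney group
  tests; matched primary/recurrent pairs classified at inclusive 2-fold
  thresholds; modified H-score (%weak + 2·%moderate + 3·%strong) and the
  combined marker score PTTG1 × 100 / LEPR.
* **Survival** (`filter_survival_cohort`, `km_estimate`, `logrank_test`,
  `cox_fit`, `dichotomize`, `combined_gene_groups`): PFS in the primary,
  treatment-naive, Simpson 1–3 subset; Kaplan–Meier, log-rank, Cox
  proportional hazards (Efron ties) with HR = exp(β) and 95% CIs;
  biomarkers cut at the median or upper quartile; the four-group combined
  PTTG1/LEPR analysis.
* **Synthetic cohorts** (`generate_cohort`, `generate_qpcr`,
  `generate_ihc`, `generate_ph_cohort`): seeded generators emulating the
  cohort structure (62 samples, 20/14/28 by grade, 208/124 planted shared
  up/down genes, batch and array-scale distortions, proportional-hazards
  PFS tied to planted PTTG1-like and LEPR-like biomarkers, Cq triplicates,
  staining fractions, 13 matched pairs), with truth tables for every
  planted quantity.

## Worked example

```r
library(meningsig)

cohort <- generate_cohort(simulation_config(seed = 42))
norm <- normalize_pipeline(cohort$expression, batch = cohort$annotation$batch)
em <- norm$matrix
em
#> ExpressionMatrix: 5000 feature(s) x 62 sample(s), log2 scale

ann <- cohort$annotation
benign <- select_samples(ann, "I", "NR")
sig <- intersect_signature(list(
  `1M+R` = de_gene_list(t_test_de(em,
    group_a = select_samples(ann, "I", c("M", "R")), group_b = benign),
    0.01, 1.25),
  `2M+R` = de_gene_list(t_test_de(em,
    group_a = select_samples(ann, "II", c("M", "R")), group_b = benign),
    0.01, 1.25),
  WHOIII = de_gene_list(t_test_de(em,
    group_a = select_samples(ann, "III"), group_b = benign),
    0.001, 1.25)))
sig
#> Malignancy signature: 278 gene(s) (177 up, 101 down)

planted <- c(cohort$truth$planted_up, cohort$truth$planted_down)
mean(planted %in% sig$genes$gene)
#> [1] 0.8373494
```

278 of the 332 planted genes are recovered (84%), with no spurious
members — the intersection trades a little sensitivity (three tests must
all fire) for a near-zero false-entry rate; the methods vignette derives
this ceiling from the noncentral-t power of the component comparisons.

The planted biomarker predicts progression in the survival-eligible
subset:

```r
surv <- filter_survival_cohort(ann)
nrow(surv)
#> [1] 43

pttg1 <- em$values[cohort$truth$pttg1_like, surv$sample_id]
grp <- dichotomize(pttg1, "median")
lr <- logrank_test(surv$pfs_months, surv$progression_event, grp)
c(chisq = lr$chisq, p = lr$p_value)
#>        chisq            p
#> 16.1149       0.0001

cox_fit(data.frame(time = surv$pfs_months,
                   event = surv$progression_event, expr = grp),
        "expr")[, c("term", "hr", "ci_lower", "ci_upper", "p_score")]
#>       term       hr ci_lower ci_upper      p_score
#> 1 exprhigh 5.214759 2.164458 12.56375 5.967483e-05
```

High expression of the hazard-increasing marker carries a hazard ratio of
about 5.2 (95% CI 2.2–12.6) for progression in this simulated cohort, in
which the true planted hazard ratio per SD is 2.

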