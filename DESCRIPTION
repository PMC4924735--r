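Package: meningsig
Title: Transcriptomic Aggressiveness Signatures and Prognostic Biomarkers in Meningioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline for identifying and validating
    aggressiveness-associated genes in meningioma from bulk expression data.
    Covers inter-array qspline normalization, median probe-set summarization,
    linear-model batch correction and median centering; per-gene two-group
    differential expression with permutation-based false discovery rate
    estimation; derivation of a cross-grade malignancy signature by
    intersecting thresholded gene lists; candidate-gene selection; relative
    quantification of qPCR Cq triplicates against dual housekeeping genes
    with Mann-Whitney subgroup comparisons; matched primary/recurrent pair
    fold-change classification; progression-free survival analysis with
    Kaplan-Meier estimation, log-rank tests, Cox proportional-hazards models
    and biomarker dichotomization; immunohistochemistry H-score and combined
    two-marker scoring; and a synthetic-cohort generator emulating the
    clinico-pathological structure of a multicenter meningioma study so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite
Config/testthat/edition: 3
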