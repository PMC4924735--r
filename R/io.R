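#' Read a tab-separated expression matrix
#'
#' Expects plain tab-separated text with the first column holding feature
#' (probe or gene) identifiers and the header row holding sample identifiers.
#' Duplicate feature rows are preserved (multiple probes per gene are
#' normal); duplicate sample columns are an error.
#'
#' @param path Path to a TSV file.
#' @param scale `"linear"` or `"log2"`, recorded on the returned object.
#' @param probe_to_gene Optional probe-to-gene map passed through to
#'   [expression_matrix()].
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, scale = c("log2", "linear"),
                                   probe_to_gene = NULL) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (ncol(raw) < 2) {
    stop("malformed header in ", path,
         ": need a feature-id column plus at least one sample column",
         call. = FALSE)
  }
  sample_ids <- colnames(raw)[-1]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup) > 0) {
    stop("duplicate sample column(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids),
                 dimnames = list(raw[[1]], sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !(col %in% c("", "NA")))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in %s, line %d, column '%s'",
                   col[bad[1]], path, bad[1] + 1L, sample_ids[j]),
           call. = FALSE)
    }
    vals[, j] <- num
  }
  expression_matrix(vals, scale = scale, probe_to_gene = probe_to_gene)
}

#' Write an expression matrix as tab-separated text
#'
#' @param em An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  df <- data.frame(feature_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# mandatory and optional annotation columns; the literal string "NA" in the
# subgroup column is a real level (no follow-up available), not missingness
ANNOTATION_MANDATORY <- c("sample_id", "who_grade", "subgroup", "simpson",
                          "followup_months", "pfs_months", "progression_event")
WHO_LEVELS <- c("I", "II", "III")
SUBGROUP_LEVELS <- c("NR", "R", "M", "NA")

#' Validate a sample annotation table
#'
#' Checks the per-sample clinical schema used throughout the pipeline:
#' WHO grade in I/II/III, clinico-pathological subgroup in NR/R/M/NA
#' (NR = no recurrence within >= 36 months of follow-up, R = recurrence at the
#' same grade, M = recurrence at a higher grade, NA = no usable follow-up or
#' incomplete resection), Simpson resection grade 1-5, non-negative follow-up
#' and progression-free survival (PFS) times with PFS <= follow-up, and the
#' rule that subgroup NA is only permitted when follow-up is missing or
#' resection was incomplete (Simpson >= 4).
#'
#' @param ann A data.frame of sample annotations.
#' @return The validated data.frame with optional columns filled with
#'   defaults, invisibly classed as `SampleAnnotation`.
#' @export
validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  missing_cols <- setdiff(ANNOTATION_MANDATORY, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ann$sample_id <- as.character(ann$sample_id)
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  ann$who_grade <- as.character(ann$who_grade)
  bad <- setdiff(unique(ann$who_grade), WHO_LEVELS)
  if (length(bad) > 0) {
    stop("unknown who_grade value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ann$subgroup <- as.character(ann$subgroup)
  ann$subgroup[is.na(ann$subgroup)] <- "NA"
  bad <- setdiff(unique(ann$subgroup), SUBGROUP_LEVELS)
  if (length(bad) > 0) {
    stop("unknown subgroup value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ann$simpson <- suppressWarnings(as.integer(ann$simpson))
  if (any(!is.na(ann$simpson) & !(ann$simpson %in% 1:5))) {
    stop("simpson grade must be 1-5 or missing", call. = FALSE)
  }
  for (col in c("followup_months", "pfs_months", "age_years")) {
    if (col %in% names(ann)) ann[[col]] <- as.numeric(ann[[col]])
  }
  if (any(ann$followup_months < 0 | ann$pfs_months < 0, na.rm = TRUE)) {
    stop("followup_months and pfs_months must be non-negative", call. = FALSE)
  }
  over <- which(!is.na(ann$pfs_months) & !is.na(ann$followup_months) &
                  ann$pfs_months > ann$followup_months)
  if (length(over) > 0) {
    stop("pfs_months exceeds followup_months for sample(s): ",
         paste(ann$sample_id[over], collapse = ", "), call. = FALSE)
  }
  for (col in c("progression_event", "treatment_naive", "is_primary")) {
    if (col %in% names(ann)) ann[[col]] <- as.logical(ann[[col]])
  }
  # subgroup NA only when no follow-up is available or resection incomplete
  bad_na <- which(ann$subgroup == "NA" &
                    !is.na(ann$followup_months) &
                    (is.na(ann$simpson) | ann$simpson < 4))
  if (length(bad_na) > 0) {
    stop("subgroup 'NA' requires missing follow-up or Simpson >= 4; ",
         "violated by sample(s): ",
         paste(ann$sample_id[bad_na], collapse = ", "), call. = FALSE)
  }
  defaults <- list(patient_id = ann$sample_id, gender = NA_character_,
                   age_years = NA_real_, treatment_naive = TRUE,
                   is_primary = TRUE, batch = "b1", center = "c1")
  for (col in names(defaults)) {
    if (!col %in% names(ann)) ann[[col]] <- defaults[[col]]
  }
  if (!all(is.na(ann$gender))) {
    bad <- setdiff(unique(ann$gender[!is.na(ann$gender)]),
                   c("male", "female"))
    if (length(bad) > 0) {
      stop("gender must be 'male' or 'female'; got: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  class(ann) <- c("SampleAnnotation", "data.frame")
  invisible(ann)
}

#' Read a sample annotation sheet
#'
#' Reads a CSV of per-sample clinical records and validates it with
#' [validate_annotation()]. The `subgroup` column uses the literal string
#' `"NA"` as a real category (no follow-up available); empty cells denote
#' missing values.
#'
#' @param path Path to a CSV file.
#' @return A validated `SampleAnnotation` data.frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ann <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", na.strings = "")
  validate_annotation(ann)
}

#' Write a sample annotation sheet
#'
#' @param ann A `SampleAnnotation` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  utils::write.csv(as.data.frame(ann), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a qPCR Cq table
#'
#' Long-format CSV with columns `sample_id`, `gene`, `replicate`, `cq`, one
#' row per technical replicate (typically triplicates). Cq values must be
#' positive and finite.
#'
#' @param path Path to a CSV file.
#' @param housekeeping Character vector of housekeeping gene names used for
#'   relative quantification (default beta-actin and GNB1).
#' @return A `QpcrTable` data.frame with a `housekeeping` attribute.
#' @export
read_qpcr_table <- function(path, housekeeping = c("ACTB", "GNB1")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  qpcr_table(df, housekeeping = housekeeping)
}

#' Construct and validate a qPCR Cq table
#'
#' @param df Long-format data.frame with columns `sample_id`, `gene`,
#'   `replicate`, `cq`.
#' @inheritParams read_qpcr_table
#' @return A `QpcrTable` data.frame.
#' @export
qpcr_table <- function(df, housekeeping = c("ACTB", "GNB1")) {
  need <- c("sample_id", "gene", "replicate", "cq")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("qPCR table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$cq <- as.numeric(df$cq)
  bad <- which(!is.finite(df$cq) | df$cq <= 0)
  if (length(bad) > 0) {
    stop("Cq values must be positive and finite (first offending row: ",
         bad[1], ")", call. = FALSE)
  }
  attr(df, "housekeeping") <- housekeeping
  class(df) <- c("QpcrTable", "data.frame")
  df
}

#' Read an immunohistochemistry staining table
#'
#' CSV with columns `sample_id`, `pct_weak`, `pct_moderate`, `pct_strong`
#' (percentages of cells staining weakly/moderately/strongly, each in
#' 0-100 with their sum at most 100) and `pttg1_count` (positive-cell count
#' in the densest high-power field).
#'
#' @param path Path to a CSV file.
#' @return An `IhcTable` data.frame.
#' @export
read_ihc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ihc_table(df)
}

#' Construct and validate an IHC staining table
#'
#' @param df Data.frame with columns `sample_id`, `pct_weak`, `pct_moderate`,
#'   `pct_strong`, `pttg1_count`.
#' @return An `IhcTable` data.frame.
#' @export
ihc_table <- function(df) {
  need <- c("sample_id", "pct_weak", "pct_moderate", "pct_strong",
            "pttg1_count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("IHC table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("pct_weak", "pct_moderate", "pct_strong")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(df[[col]] < 0 | df[[col]] > 100, na.rm = TRUE)) {
      stop(col, " must lie in [0, 100]", call. = FALSE)
    }
  }
  tot <- df$pct_weak + df$pct_moderate + df$pct_strong
  if (any(tot > 100 + 1e-9, na.rm = TRUE)) {
    stop("staining percentages sum above 100 for sample(s): ",
         paste(df$sample_id[which(tot > 100 + 1e-9)], collapse = ", "),
         call. = FALSE)
  }
  df$pttg1_count <- as.numeric(df$pttg1_count)
  if (any(df$pttg1_count < 0 | df$pttg1_count != round(df$pttg1_count),
          na.rm = TRUE)) {
    stop("pttg1_count must be a non-negative integer", call. = FALSE)
  }
  class(df) <- c("IhcTable", "data.frame")
  df
}

#' Read a GEO series-matrix file
#'
#' Parses the plain-text series-matrix format distributed by the Gene
#' Expression Omnibus: `!Sample_*` metadata lines plus the expression table
#' between `!series_matrix_table_begin` and `!series_matrix_table_end`.
#' `!Sample_characteristics_ch1` lines of the form `key: value` are spread
#' into one metadata column per key. The reader is tolerant: any clinical
#' field that is absent simply yields an NA column, so downstream annotation
#' building can proceed with whatever metadata the series carries.
#'
#' @param path Path to an (uncompressed) series-matrix text file.
#' @param scale Scale flag for the embedded expression table.
#' @return A list with `expression` (an `ExpressionMatrix`) and `metadata`
#'   (a data.frame with one row per sample).
#' @export
read_geo_series_matrix <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^!Sample_", lines, value = TRUE)
  split_fields <- function(line) {
    parts <- strsplit(sub("^!", "", line), "\t")[[1]]
    gsub('^"|"$', "", parts)
  }
  meta <- list()
  char_idx <- 0L
  for (line in meta_lines) {
    parts <- split_fields(line)
    key <- parts[1]
    vals <- parts[-1]
    if (key == "Sample_characteristics_ch1") {
      # characteristics lines repeat; keep 'key: value' pairs as columns
      kv <- regmatches(vals, regexec("^\\s*([^:]+):\\s*(.*)$", vals))
      keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else "", "")
      vv <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_,
                   "")
      key_name <- unique(keys[keys != ""])
      if (length(key_name) == 1) {
        meta[[make.names(key_name)]] <- vv
      } else {
        char_idx <- char_idx + 1L
        meta[[paste0("characteristics_", char_idx)]] <- vals
      }
    } else if (is.null(meta[[sub("^Sample_", "", key)]])) {
      meta[[sub("^Sample_", "", key)]] <- vals
    }
  }
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
    stop("no expression table found in ", path, call. = FALSE)
  }
  tbl <- utils::read.delim(text = lines[(begin + 1):(end - 1)],
                           check.names = FALSE, quote = '"')
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(vals) <- as.character(tbl[[1]])
  storage.mode(vals) <- "double"
  metadata <- as.data.frame(meta, stringsAsFactors = FALSE,
                            check.names = FALSE)
  if (nrow(metadata) > 0 && "geo_accession" %in% names(metadata)) {
    metadata$sample_id <- metadata$geo_accession
  }
  list(expression = expression_matrix(vals, scale = scale),
       metadata = metadata)
}
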