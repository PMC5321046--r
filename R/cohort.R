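#' Load and validate a cohort demographics table
#'
#' Reads a CSV or TSV file with one row per subject and the columns
#' `subject_id`, `age_months`, `sex` (`M`/`F`), `field_strength` (`1.5` or
#' `3`), `resolution` (mean voxel edge in mm), `cnr` (contrast-to-noise
#' indicator) and `inr` (inhomogeneity-to-noise indicator). Row order is the
#' canonical subject order for all tissue stacks.
#'
#' @param path File path; tab-delimited files are detected by a `.tsv`
#'   extension or an embedded tab in the header.
#' @param min_age_months,max_age_months Optional age-range screen; subjects
#'   outside `[min, max]` are dropped (with a report in attribute
#'   `"age_screen"`).
#' @return A `cohort_table` data frame.
#' @export
load_cohort_table <- function(path, min_age_months = NULL, max_age_months = NULL) {
  if (!file.exists(path)) stop(sprintf("cohort table not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE) || grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  cohort_table(df, min_age_months = min_age_months, max_age_months = max_age_months)
}

#' Construct a validated cohort table from a data frame
#'
#' @param df Data frame with the columns documented in
#'   [load_cohort_table()].
#' @inheritParams load_cohort_table
#' @return A `cohort_table` data frame.
#' @export
cohort_table <- function(df, min_age_months = NULL, max_age_months = NULL) {
  required <- c("subject_id", "age_months", "sex", "field_strength",
                "resolution", "cnr", "inr")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("cohort table is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stop(sprintf("duplicate subject_id(s): %s", paste(unique(dup), collapse = ", ")))
  age <- suppressWarnings(as.numeric(df$age_months))
  bad <- which(!is.finite(age) | age <= 0)
  if (length(bad))
    stop(sprintf("unparsable or non-positive age_months for subject(s): %s",
                 paste(df$subject_id[bad], collapse = ", ")))
  df$age_months <- age
  sx <- toupper(trimws(as.character(df$sex)))
  bad <- which(!sx %in% c("M", "F"))
  if (length(bad))
    stop(sprintf("sex must be M or F; offending subject(s): %s",
                 paste(df$subject_id[bad], collapse = ", ")))
  df$sex <- sx
  fs <- suppressWarnings(as.numeric(df$field_strength))
  bad <- which(!fs %in% c(1.5, 3))
  if (length(bad))
    stop(sprintf("field_strength must be 1.5 or 3; offending subject(s): %s",
                 paste(df$subject_id[bad], collapse = ", ")))
  df$field_strength <- fs
  for (col in c("resolution", "cnr", "inr")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-finite %s for subject(s): %s", col,
                   paste(df$subject_id[bad], collapse = ", ")))
    if (col == "resolution" && any(v <= 0))
      stop("resolution must be positive")
    df[[col]] <- v
  }
  screen <- NULL
  keep <- rep(TRUE, nrow(df))
  if (!is.null(min_age_months)) keep <- keep & df$age_months >= min_age_months
  if (!is.null(max_age_months)) keep <- keep & df$age_months <= max_age_months
  if (!all(keep)) {
    screen <- df$subject_id[!keep]
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  out <- structure(df, class = c("cohort_table", "data.frame"))
  attr(out, "age_screen") <- screen
  out
}

#' Combined per-subject data-quality indicator
#'
#' Sums the z-transformed quality indicators (voxel resolution, CNR, INR),
#' oriented so that larger values mean better data: the resolution z-score is
#' negated (smaller voxels = better), CNR and INR are taken as
#' higher-is-better. Constant columns contribute 0. The result is invariant
#' to affine rescaling of any raw indicator column.
#'
#' @param table A `cohort_table`.
#' @param orientation Named numeric vector of signs applied to the z-scores
#'   of `resolution`, `cnr` and `inr`.
#' @return Numeric vector (z-units), one value per subject.
#' @export
quality_indicator <- function(table,
                              orientation = c(resolution = -1, cnr = 1, inr = 1)) {
  if (nrow(table) < 2L)
    stop("quality_indicator needs at least 2 subjects")
  stopifnot(all(c("resolution", "cnr", "inr") %in% names(orientation)))
  zsum <- rep(0, nrow(table))
  for (col in c("resolution", "cnr", "inr")) {
    v <- table[[col]]
    s <- stats::sd(v)
    z <- if (is.finite(s) && s > 0) (v - mean(v)) / s else rep(0, length(v))
    zsum <- zsum + orientation[[col]] * z
  }
  zsum
}

#' Remove subjects from inadequately covered age brackets
#'
#' Subjects falling into any half-open age bracket
#' `[k * bracket_months, (k + 1) * bracket_months)` (anchored at 0) that
#' contains fewer than `min_n` subjects are removed. The removed brackets and
#' subjects are reported in attribute `"bracket_report"`.
#'
#' @param table A `cohort_table`.
#' @param bracket_months Bracket width in months (default: 24, i.e. 2 years).
#' @param min_n Minimum subjects required per bracket (default: 20).
#' @return The filtered `cohort_table`.
#' @export
age_bracket_filter <- function(table, bracket_months = 24L, min_n = 20L) {
  stopifnot(bracket_months > 0)
  bracket <- floor(table$age_months / bracket_months)
  counts <- table(bracket)
  bad <- as.numeric(names(counts))[counts < min_n]
  keep <- !(bracket %in% bad)
  if (!any(keep))
    stop("no bracket adequately covered")
  removed <- data.frame(bracket_start_months = bad * bracket_months,
                        bracket_end_months = (bad + 1) * bracket_months,
                        n = as.integer(counts[as.character(bad)]))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  attr(out, "bracket_report") <- list(removed_brackets = removed,
                                      removed_subjects = table$subject_id[!keep])
  out
}

#' Canonical column order of the spline design matrix
#' @export
design_columns <- c("age_months", "sex", "field_strength", "quality")

#' Build the demographic design matrix
#'
#' Fixed column order `age_months` (continuous, months), `sex` (male = 1,
#' female = 0), `field_strength` (3 T = 1, 1.5 T = 0) and `quality`
#' (continuous, z-units; computed with [quality_indicator()] unless
#' supplied).
#'
#' @param table A `cohort_table`.
#' @param quality Optional precomputed per-subject quality values.
#' @return Numeric matrix with `nrow(table)` rows, subject ids as row names.
#' @export
build_design_matrix <- function(table, quality = NULL) {
  if (is.null(quality)) quality <- quality_indicator(table)
  stopifnot(length(quality) == nrow(table), all(is.finite(quality)))
  X <- cbind(age_months = table$age_months,
             sex = as.numeric(table$sex == "M"),
             field_strength = as.numeric(table$field_strength == 3),
             quality = as.numeric(quality))
  rownames(X) <- table$subject_id
  X
}
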