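#' Sample annotation levels
#'
#' Controlled vocabularies for the three grouping variables: histological
#' subtype, TCGA-surrogate molecular subtype, and CTNNB1 (beta-catenin)
#' mutation status. `"unknown"` marks samples without a molecular or
#' CTNNB1 call (not every sample is subtyped or sequenced).
#' @name annotation_levels
#' @keywords internal
NULL

HISTOLOGY_LEVELS <- c("endometrioid", "serous", "clear_cell", "dedifferentiated")
MOLECULAR_LEVELS <- c("MMRd", "POLE", "p53wt", "p53abn")
CTNNB1_LEVELS <- c("mutated", "wildtype")
GRADE_LEVELS <- c("G1", "G2", "G3")

#' Validate a sample annotation table
#'
#' Checks the contract for per-sample subtype labels: unique `sample_id`,
#' a histology label for every sample, grade only for endometrioid tumors,
#' and molecular / CTNNB1 status drawn from the controlled vocabulary
#' (with `"unknown"` allowed).
#'
#' @param ann A data frame with columns `sample_id`, `histology`, `grade`,
#'   `molecular`, `ctnnb1`.
#' @return The validated annotation tibble, invisibly usable in pipes.
#' @export
validate_annotations <- function(ann) {
  ann <- tibble::as_tibble(ann)
  needed <- c("sample_id", "histology", "grade", "molecular", "ctnnb1")
  missing_cols <- setdiff(needed, names(ann))
  if (length(missing_cols)) {
    abort(sprintf("Annotation table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "mirsubtype_format_error")
  }
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup)) abort(sprintf("Duplicated sample id(s): %s", paste(dup, collapse = ", ")),
                         class = "mirsubtype_format_error")
  bad_hist <- setdiff(unique(ann$histology), HISTOLOGY_LEVELS)
  if (length(bad_hist) || anyNA(ann$histology)) {
    abort(sprintf("Every sample needs a histology in {%s}; offending value(s): %s",
                  paste(HISTOLOGY_LEVELS, collapse = ", "),
                  paste(c(bad_hist, if (anyNA(ann$histology)) "NA"), collapse = ", ")),
          class = "mirsubtype_validation_error")
  }
  bad_mol <- setdiff(unique(ann$molecular), c(MOLECULAR_LEVELS, "unknown"))
  if (length(bad_mol)) abort(sprintf("Unknown molecular label(s): %s", paste(bad_mol, collapse = ", ")),
                             class = "mirsubtype_validation_error")
  bad_ct <- setdiff(unique(ann$ctnnb1), c(CTNNB1_LEVELS, "unknown"))
  if (length(bad_ct)) abort(sprintf("Unknown ctnnb1 label(s): %s", paste(bad_ct, collapse = ", ")),
                            class = "mirsubtype_validation_error")
  graded <- !is.na(ann$grade) & ann$grade != "unknown"
  if (any(graded & ann$histology != "endometrioid")) {
    abort("Grade may only be recorded for endometrioid samples.",
          class = "mirsubtype_validation_error")
  }
  bad_grade <- setdiff(unique(ann$grade[graded]), GRADE_LEVELS)
  if (length(bad_grade)) abort(sprintf("Unknown grade(s): %s", paste(bad_grade, collapse = ", ")),
                               class = "mirsubtype_validation_error")
  ann
}

#' Read / write sample annotations
#'
#' TSV with columns `sample_id`, `histology`, `grade`, `molecular`,
#' `ctnnb1`; unknown molecular / CTNNB1 status written as `"unknown"`,
#' absent grade as `NA`.
#'
#' @param path File path.
#' @return For `read_annotations`, a validated annotation tibble.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_annotations(ann)
}

#' @rdname read_annotations
#' @param ann Annotation tibble.
#' @export
write_annotations <- function(ann, path) {
  readr::write_tsv(validate_annotations(ann), path, na = "NA")
  invisible(path)
}

#' Build a one-vs-rest group contrast
#'
#' Positives are the samples carrying `level` for `variable`; negatives
#' are all other samples with a *known* value of that variable. Samples
#' whose value is unknown are excluded from both sides rather than pooled
#' into the control group, so an incompletely subtyped cohort does not
#' contaminate the null group.
#'
#' @param ann Annotation tibble (see [validate_annotations()]).
#' @param variable One of `"histology"`, `"molecular"`, `"ctnnb1"`.
#' @param level A valid level of `variable`, e.g. `"serous"` or `"MMRd"`.
#' @param samples Optional character vector restricting the contrast to a
#'   subset of sample ids (e.g. the columns of an expression matrix).
#' @return A `group_contrast`: list with `name`, `positive_ids`,
#'   `negative_ids`.
#' @export
make_contrast <- function(ann, variable = c("histology", "molecular", "ctnnb1"),
                          level, samples = NULL) {
  variable <- match.arg(variable)
  ann <- validate_annotations(ann)
  valid <- switch(variable,
                  histology = HISTOLOGY_LEVELS,
                  molecular = MOLECULAR_LEVELS,
                  ctnnb1 = CTNNB1_LEVELS)
  if (!level %in% valid) {
    abort(sprintf("'%s' is not a level of %s (expected one of: %s).",
                  level, variable, paste(valid, collapse = ", ")),
          class = "mirsubtype_contrast_error")
  }
  if (!is.null(samples)) ann <- ann[ann$sample_id %in% samples, , drop = FALSE]
  value <- ann[[variable]]
  known <- !is.na(value) & value != "unknown"
  pos <- ann$sample_id[known & value == level]
  neg <- ann$sample_id[known & value != level]
  new_contrast(paste0(variable, ":", level), pos, neg)
}

#' @rdname make_contrast
#' @param name Contrast label.
#' @param positive_ids,negative_ids Disjoint, non-empty sample id sets.
#' @export
new_contrast <- function(name, positive_ids, negative_ids) {
  positive_ids <- as.character(positive_ids)
  negative_ids <- as.character(negative_ids)
  if (length(intersect(positive_ids, negative_ids))) {
    abort("Contrast groups overlap.", class = "mirsubtype_contrast_error")
  }
  if (length(positive_ids) < 2L || length(negative_ids) < 2L) {
    abort(sprintf("Contrast '%s' needs at least 2 samples per group (got %d vs %d); the t-test is undefined otherwise.",
                  name, length(positive_ids), length(negative_ids)),
          class = "mirsubtype_contrast_error")
  }
  structure(list(name = name,
                 positive_ids = positive_ids,
                 negative_ids = negative_ids),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("<group_contrast> %s: %d positives vs %d negatives\n",
              x$name, length(x$positive_ids), length(x$negative_ids)))
  invisible(x)
}

# Align a contrast with the columns of an expression matrix; returns
# list(expr_matrix, y) with y = 1 for positives, 0 for negatives.
contrast_design <- function(expr, contrast) {
  m <- wide_to_matrix(expr)
  ids <- c(contrast$positive_ids, contrast$negative_ids)
  missing_ids <- setdiff(ids, colnames(m))
  if (length(missing_ids)) {
    abort(sprintf("Contrast sample(s) absent from expression matrix: %s",
                  paste(missing_ids, collapse = ", ")),
          class = "mirsubtype_contrast_error")
  }
  m <- m[, ids, drop = FALSE]
  y <- c(rep(1L, length(contrast$positive_ids)),
         rep(0L, length(contrast$negative_ids)))
  list(x = m, y = y)
}
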