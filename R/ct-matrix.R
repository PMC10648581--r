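#' Construct a raw Ct matrix
#'
#' A raw Ct matrix is a wide tibble: first column `assay_id`, one numeric
#' column per sample, holding RT-qPCR quantification-cycle (Ct) values.
#' Rows flagged as spike-ins are synthetic controls added at known amount;
#' they carry the per-sample technical signal used by [normalize_ct()].
#'
#' @param x A data frame with an `assay_id` first column and one numeric
#'   column per sample. Missing Ct values are `NA`.
#' @param spike_in_ids Character vector of assay ids that are spike-in
#'   controls. Must be a subset of `assay_id`.
#' @return A `ct_matrix` tibble with a `spike_in_ids` attribute.
#' @export
ct_matrix <- function(x, spike_in_ids = character()) {
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) abort("A Ct matrix needs an `assay_id` column plus at least one sample column.")
  names(x)[1L] <- "assay_id"
  x$assay_id <- as.character(x$assay_id)
  validate_ct_matrix(x, spike_in_ids)
  structure(x,
            spike_in_ids = as.character(spike_in_ids),
            class = c("ct_matrix", class(tibble::tibble())))
}

validate_ct_matrix <- function(x, spike_in_ids) {
  assays <- x[[1L]]
  samples <- names(x)[-1L]
  dup_a <- unique(assays[duplicated(assays)])
  if (length(dup_a)) {
    abort(sprintf("Duplicated assay id(s): %s", paste(dup_a, collapse = ", ")),
          class = "mirsubtype_format_error")
  }
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    abort(sprintf("Duplicated sample id(s): %s", paste(dup_s, collapse = ", ")),
          class = "mirsubtype_format_error")
  }
  bad_spike <- setdiff(spike_in_ids, assays)
  if (length(bad_spike)) {
    abort(sprintf("spike_in_ids not present among assays: %s",
                  paste(bad_spike, collapse = ", ")),
          class = "mirsubtype_format_error")
  }
  for (s in samples) {
    col <- x[[s]]
    if (!is.numeric(col)) {
      abort(sprintf("Sample column '%s' is not numeric.", s),
            class = "mirsubtype_format_error")
    }
    out_of_range <- which(!is.na(col) & (col < 0 | col > 45))
    if (length(out_of_range)) {
      i <- out_of_range[1L]
      abort(sprintf("Ct value %.3f outside [0, 45] at assay '%s', sample '%s'.",
                    col[i], assays[i], s),
            class = "mirsubtype_validation_error")
    }
  }
  invisible(x)
}

#' Spike-in assay ids of a Ct matrix
#' @param x A `ct_matrix`.
#' @return Character vector of spike-in assay ids.
#' @export
spike_in_ids <- function(x) attr(x, "spike_in_ids") %||% character()

#' Read a Ct matrix from TSV
#'
#' Expects a UTF-8 TSV whose first column is `assay_id` and whose remaining
#' columns are one per sample; missing Ct values are empty cells or `NA`.
#' Rows whose assay id starts with `spike_in_prefix` are flagged as
#' spike-in controls.
#'
#' @param path Path to the TSV file.
#' @param spike_in_prefix Prefix identifying spike-in control rows
#'   (default `"SPIKE_"`).
#' @return A [ct_matrix()] tibble.
#' @export
read_ct_matrix <- function(path, spike_in_prefix = "SPIKE_") {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), name_repair = "minimal")
  if (ncol(raw) < 2L) abort("Ct matrix TSV needs an assay id column and at least one sample column.",
                            class = "mirsubtype_format_error")
  dup_s <- unique(names(raw)[-1L][duplicated(names(raw)[-1L])])
  if (length(dup_s)) {
    abort(sprintf("Duplicated sample id(s): %s", paste(dup_s, collapse = ", ")),
          class = "mirsubtype_format_error")
  }
  assays <- raw[[1L]]
  num <- raw[-1L]
  for (s in names(num)) {
    col <- num[[s]]
    parsed <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & col != "" & col != "NA" & is.na(parsed))
    if (length(bad)) {
      abort(sprintf("Non-numeric Ct value '%s' at assay '%s', sample '%s'.",
                    col[bad[1L]], assays[bad[1L]], s),
            class = "mirsubtype_format_error")
    }
    num[[s]] <- parsed
  }
  spikes <- assays[startsWith(assays, spike_in_prefix)]
  ct_matrix(dplyr::bind_cols(tibble::tibble(assay_id = assays), num),
            spike_in_ids = spikes)
}

#' Write a Ct matrix to TSV
#'
#' Inverse of [read_ct_matrix()]: round-trips values losslessly (full
#' double precision, missing values as `NA`).
#'
#' @param x A `ct_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_matrix <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "NA")
  invisible(path)
}

#' Normalize Ct values against spike-in controls
#'
#' Converts quantification cycles to log2 relative expression using the
#' per-sample median spike-in Ct as the technical reference:
#' `expression(m, s) = median(spike-in Ct in s) - ct(m, s)`, so higher
#' expression means more abundant and the result is invariant under
#' per-sample additive Ct shifts. Ct values at or above `detection_limit`,
#' or missing, are treated as undetected. miRNAs undetected in more than
#' `max_missing_frac` of samples are dropped; remaining undetected entries
#' are imputed at that miRNA's minimum observed expression minus 1.
#' Spike-in rows are removed from the output.
#'
#' @param raw A [ct_matrix()] with at least one spike-in assay observed in
#'   every sample.
#' @param detection_limit Ct cycles above which an assay is called
#'   undetected (default 38).
#' @param max_missing_frac Maximum tolerated fraction of undetected samples
#'   per miRNA before the miRNA is dropped (default 0.2).
#' @return A `mirna_expr` tibble: first column `mirna_id`, one numeric
#'   column of finite log2 relative expression per sample.
#' @export
normalize_ct <- function(raw, detection_limit = 38, max_missing_frac = 0.2) {
  assert_scalar_number(detection_limit, "detection_limit", 0, 45)
  assert_scalar_number(max_missing_frac, "max_missing_frac", 0, 1)
  spikes <- spike_in_ids(raw)
  if (!length(spikes)) abort("No spike-in assays flagged; cannot normalize.",
                             class = "mirsubtype_validation_error")
  ct <- wide_to_matrix(raw)
  spike_ct <- ct[rownames(ct) %in% spikes, , drop = FALSE]
  ref <- apply(spike_ct, 2L, stats::median, na.rm = TRUE)
  no_ref <- names(ref)[!is.finite(ref)]
  if (length(no_ref)) {
    abort(sprintf("Sample(s) with no usable spike-in Ct: %s",
                  paste(no_ref, collapse = ", ")),
          class = "mirsubtype_validation_error")
  }
  mir <- ct[!(rownames(ct) %in% spikes), , drop = FALSE]
  undetected <- is.na(mir) | mir >= detection_limit
  expr <- sweep(-mir, 2L, ref, FUN = "+")  # ref - ct
  expr[undetected] <- NA_real_

  frac_undet <- rowMeans(undetected)
  keep <- frac_undet <= max_missing_frac & frac_undet < 1
  expr <- expr[keep, , drop = FALSE]
  # impute what remains undetected at the miRNA's observed floor minus one cycle
  for (i in which(rowSums(is.na(expr)) > 0L)) {
    floor_i <- min(expr[i, ], na.rm = TRUE) - 1
    expr[i, is.na(expr[i, ])] <- floor_i
  }
  out <- matrix_to_wide(expr, "mirna_id")
  structure(out, class = c("mirna_expr", class(tibble::tibble())))
}

#' Read / write a log2 expression matrix
#'
#' Same TSV layout as the Ct matrix, first column `mirna_id`.
#'
#' @param path File path.
#' @return For `read_expression_matrix`, a `mirna_expr` tibble.
#' @export
read_expression_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(), .default = readr::col_double()))
  names(x)[1L] <- "mirna_id"
  dup <- unique(x$mirna_id[duplicated(x$mirna_id)])
  if (length(dup)) abort(sprintf("Duplicated miRNA id(s): %s", paste(dup, collapse = ", ")),
                         class = "mirsubtype_format_error")
  structure(x, class = c("mirna_expr", class(tibble::tibble())))
}

#' @rdname read_expression_matrix
#' @param x A `mirna_expr` tibble.
#' @export
write_expression_matrix <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "NA")
  invisible(path)
}
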