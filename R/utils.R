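# Internal helpers shared across the package.

#' @importFrom rlang abort warn %||% .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib mirsubtype, .registration = TRUE
NULL

# Deterministic 31-bit seed derived from a base seed and a path of labels.
# Keeps every stage / repeat / contrast on an independent, reproducible
# stream without user-level seed bookkeeping.
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, keeps results in R's integer range
  h <- as.double(seed) %% m
  for (part in as.character(unlist(list(...)))) {
    for (code in utf8ToInt(part)) {
      h <- (h * 131 + code) %% m
    }
    h <- (h * 31 + 7) %% m
  }
  as.integer(h)
}

# First column name expected for each wide-table flavour.
.id_col <- function(x) names(x)[1L]

# Extract the numeric sample-value matrix from a wide tibble whose first
# column holds row identifiers. Rows named by ids, columns by sample ids.
wide_to_matrix <- function(x) {
  ids <- as.character(x[[1L]])
  m <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(m)) storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_wide <- function(m, id_col) {
  out <- tibble::as_tibble(m, rownames = id_col)
  out
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)))
  }
  invisible(x)
}
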