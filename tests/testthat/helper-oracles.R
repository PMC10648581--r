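# Shared fixtures and independent oracles for the suite.

# Wrap a miRNA x sample matrix (or named row list) as a mirna_expr tibble.
as_expr <- function(m) {
  if (is.list(m) && !is.data.frame(m)) m <- do.call(rbind, m)
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  structure(tibble::as_tibble(m, rownames = "mirna_id"),
            class = c("mirna_expr", class(tibble::tibble())))
}

# Two-group contrast over the first n1 columns of an expression tibble.
split_contrast <- function(expr, n1, name = "test") {
  ids <- names(expr)[-1L]
  new_contrast(name, ids[seq_len(n1)], ids[-seq_len(n1)])
}

# Independent permutation oracle: exhaustive enumeration of all
# positive-set assignments, t statistics via stats::t.test.
enumerate_perm_p <- function(values, n1) {
  tstat <- function(idx) {
    unname(stats::t.test(values[idx], values[-idx], var.equal = TRUE)$statistic)
  }
  t_obs <- abs(tstat(seq_len(n1)))
  assignments <- utils::combn(length(values), n1)
  t_all <- abs(apply(assignments, 2L, tstat))
  mean(t_all >= t_obs - 1e-8)
}

# Independent AUC oracle: brute-force concordant-pair counting.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Small synthetic cohort config used across tests: trimmed panel and
# cohort so unit tests stay fast while keeping the full group structure.
small_cohort_config <- function(..., effects = NULL, seed = 42L) {
  cohort_config(
    n_mirnas = 40, n_spikeins = 6,
    histology_sizes = c(endometrioid = 20, serous = 6, clear_cell = 6,
                        dedifferentiated = 4),
    molecular_sizes = c(MMRd = 12, POLE = 4, p53wt = 10, p53abn = 4),
    ctnnb1_n_mutated = 5, n_sequenced = 28,
    effects = effects, seed = seed, ...)
}

# Canonical JSON rendering of a fitted model, for determinism checks.
model_json <- function(model) {
  jsonlite::toJSON(mirsubtype:::model_as_list(model), auto_unbox = TRUE,
                   digits = NA)
}
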