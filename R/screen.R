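# One-vs-rest differential-expression screen: fold change, pooled-variance
# Student t, permutation p-values, significance and fold-change filters.

#' Fold change of one miRNA for a contrast
#'
#' Ratio of geometric means: `2^(mean log2 in positives - mean log2 in
#' negatives)`, matching the log2 domain of the t statistic.
#'
#' @param expr A `mirna_expr` tibble (see [normalize_ct()]).
#' @param contrast A [make_contrast()] result.
#' @param mirna_id miRNA to evaluate.
#' @return Positive scalar fold change.
#' @export
fold_change <- function(expr, contrast, mirna_id) {
  d <- contrast_design(expr, contrast)
  v <- mirna_row(d, mirna_id)
  2^(mean(v[d$y == 1L]) - mean(v[d$y == 0L]))
}

#' Pooled-variance Student t statistic
#'
#' Two-sample equal-variance t on log2 expression, positive when the
#' positive group's mean is higher. Zero pooled variance yields 0 when
#' the means agree and a signed infinity sentinel otherwise.
#'
#' @inheritParams fold_change
#' @return Scalar t statistic.
#' @export
student_t <- function(expr, contrast, mirna_id) {
  d <- contrast_design(expr, contrast)
  v <- mirna_row(d, mirna_id)
  pooled_t_stats(matrix(v, nrow = 1L), d$y == 1L)
}

mirna_row <- function(d, mirna_id) {
  if (!mirna_id %in% rownames(d$x)) {
    abort(sprintf("miRNA '%s' not present in expression matrix.", mirna_id),
          class = "mirsubtype_validation_error")
  }
  d$x[mirna_id, ]
}

# Pooled-variance t statistics for every row of `x` (miRNAs x samples)
# given a logical positive-group indicator. Vectorized over rows.
pooled_t_stats <- function(x, pos) {
  n1 <- sum(pos); n2 <- sum(!pos)
  m1 <- rowMeans(x[, pos, drop = FALSE])
  m2 <- rowMeans(x[, !pos, drop = FALSE])
  ss1 <- rowSums(x[, pos, drop = FALSE]^2) - n1 * m1^2
  ss2 <- rowSums(x[, !pos, drop = FALSE]^2) - n2 * m2^2
  pooled <- pmax((ss1 + ss2) / (n1 + n2 - 2), 0)  # guard tiny negative cancellation
  se <- sqrt(pooled * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  degenerate <- !is.finite(t) | pooled < 1e-12
  if (any(degenerate)) {
    diff <- (m1 - m2)[degenerate]
    t[degenerate] <- ifelse(abs(diff) < 1e-12, 0, sign(diff) * Inf)
  }
  unname(t)
}

# t statistics for all rows under B column-label assignments.
# `memberships` is an n x B logical/0-1 matrix marking positives.
# Returns an m x B matrix. Uses matrix products so a full 352 x 119
# screen with B = 1000 costs two dense multiplications.
perm_t_matrix <- function(x, memberships) {
  n <- ncol(x)
  n1 <- colSums(memberships)
  n2 <- n - n1
  s1 <- x %*% memberships                    # m x B group sums
  q1 <- (x^2) %*% memberships
  tot <- rowSums(x)
  qtot <- rowSums(x^2)
  m1 <- sweep(s1, 2L, n1, "/")
  m2 <- sweep(-s1, 1L, tot, "+")
  m2 <- sweep(m2, 2L, n2, "/")
  ss1 <- q1 - sweep(m1^2, 2L, n1, "*")
  ss2 <- sweep(-q1, 1L, qtot, "+") - sweep(m2^2, 2L, n2, "*")
  pooled <- pmax((ss1 + ss2) / (n - 2), 0)  # guard tiny negative cancellation
  se <- sqrt(sweep(pooled, 2L, 1 / n1 + 1 / n2, "*"))
  t <- (m1 - m2) / se
  degenerate <- !is.finite(t) | pooled < 1e-12
  if (any(degenerate)) {
    diff <- (m1 - m2)[degenerate]
    t[degenerate] <- ifelse(abs(diff) < 1e-12, 0, sign(diff) * Inf)
  }
  t
}

# Column membership matrix for the permutation null. When the assignment
# space choose(n, n1) fits within B, enumerate it exhaustively (exact
# test); otherwise draw B uniform reassignments preserving group sizes.
perm_memberships <- function(n, n1, B, seed) {
  n_space <- suppressWarnings(choose(n, n1))
  if (is.finite(n_space) && n_space <= B) {
    idx <- utils::combn(n, n1)
    mem <- matrix(0, n, ncol(idx))
    mem[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- 1
    list(memberships = mem, exact = TRUE)
  } else {
    mem <- matrix(0, n, B)
    withr::with_seed(seed, {
      for (b in seq_len(B)) mem[sample.int(n, n1), b] <- 1
    })
    list(memberships = mem, exact = FALSE)
  }
}

# Shared p-value rule. Exact mode: proportion of the enumerated space at
# least as extreme (the observed assignment is in the space, so p > 0).
# Sampled mode: the (b + 1) / (B + 1) estimator, never 0.
perm_p_from_t <- function(t_obs, t_perm, exact) {
  tol <- 1e-8
  extreme <- abs(t_perm) >= (abs(t_obs) - tol) |
    (is.infinite(t_obs) & is.infinite(t_perm))
  hits <- rowSums(extreme)
  if (exact) hits / ncol(t_perm) else (1 + hits) / (ncol(t_perm) + 1)
}

#' Permutation p-value for one miRNA
#'
#' Two-sided permutation test of the pooled-variance t statistic under
#' uniform reassignment of the positive/negative labels preserving group
#' sizes. Uses the `(b + 1) / (B + 1)` estimator, so p is never 0; when
#' the assignment space has at most `B` distinct assignments the space is
#' enumerated exhaustively and the exact proportion returned.
#'
#' @inheritParams fold_change
#' @param B Number of label permutations (default 1000).
#' @param seed Integer seed making the draw reproducible.
#' @return p-value in `(0, 1]`, at least `1 / (B + 1)`.
#' @export
permutation_p <- function(expr, contrast, mirna_id, B = 1000, seed = 1L) {
  if (!is.numeric(B) || length(B) != 1L || B < 1) {
    abort("B must be a positive permutation count.",
          class = "mirsubtype_parameter_error")
  }
  d <- contrast_design(expr, contrast)
  v <- matrix(mirna_row(d, mirna_id), nrow = 1L)
  t_obs <- pooled_t_stats(v, d$y == 1L)
  pm <- perm_memberships(length(d$y), sum(d$y), B, derive_seed(seed, "perm", contrast$name))
  t_perm <- perm_t_matrix(v, pm$memberships)
  perm_p_from_t(t_obs, t_perm, pm$exact)
}

#' Run the one-vs-rest differential screen
#'
#' Computes, for every miRNA in the matrix, the fold change (ratio of
#' geometric means), the pooled-variance t statistic, and the two-sided
#' permutation p-value under a shared set of `B` label reassignments.
#' Records are returned for all tested miRNAs; `significant` flags
#' `perm_p < alpha` and `passes_fc_filter` flags `|fold_change - 1| >
#' fc_threshold`. No multiple-testing correction is applied; the number
#' tested is recorded so users can post-correct.
#'
#' @inheritParams fold_change
#' @param alpha Significance level on the permutation p (default 0.05).
#' @param B Number of permutations (default 1000).
#' @param fc_threshold Fold-change filter threshold on `|FC - 1|`
#'   (default 0.5, i.e. keep FC > 1.5 or < 0.5).
#' @param seed Integer seed for the permutation draw.
#' @return A `mirna_screen` tibble, one row per miRNA, with columns
#'   `mirna_id`, `fold_change`, `t_stat`, `perm_p`, `direction`,
#'   `significant`, `passes_fc_filter`; screen parameters are attached as
#'   attributes and surfaced by [glance()].
#' @export
run_screen <- function(expr, contrast, alpha = 0.05, B = 1000,
                       fc_threshold = 0.5, seed = 1L) {
  assert_scalar_number(alpha, "alpha", 0, 1)
  if (!is.numeric(B) || length(B) != 1L || B < 1) {
    abort("B must be a positive permutation count.",
          class = "mirsubtype_parameter_error")
  }
  d <- contrast_design(expr, contrast)
  pos <- d$y == 1L
  fc <- 2^(rowMeans(d$x[, pos, drop = FALSE]) - rowMeans(d$x[, !pos, drop = FALSE]))
  t_obs <- pooled_t_stats(d$x, pos)
  pm <- perm_memberships(length(pos), sum(pos), B,
                         derive_seed(seed, "perm", contrast$name))
  t_perm <- perm_t_matrix(d$x, pm$memberships)
  p <- perm_p_from_t(t_obs, t_perm, pm$exact)

  rec <- tibble::tibble(
    mirna_id = rownames(d$x),
    fold_change = unname(fc),
    t_stat = t_obs,
    perm_p = p,
    direction = ifelse(fc > 1, "increased", "decreased"),
    significant = p < alpha,
    passes_fc_filter = abs(fc - 1) > fc_threshold
  )
  structure(rec,
            contrast_name = contrast$name,
            n_positive = sum(pos), n_negative = sum(!pos),
            alpha = alpha, n_permutations = as.integer(B),
            exact_permutations = pm$exact,
            fc_threshold = fc_threshold, seed = as.integer(seed),
            class = c("mirna_screen", class(rec)))
}

#' Fold-change filter
#'
#' Keeps records with `|fold_change - 1| > fc_threshold` (strictly), i.e.
#' fold change above `1 + fc_threshold` or below `1 - fc_threshold`; at
#' the default 0.5 that is FC > 1.5 or FC < 0.5, and a fold change of
#' exactly 1.5 is excluded.
#'
#' @param records A tibble with a `fold_change` column (e.g. a
#'   [run_screen()] result).
#' @param fc_threshold Threshold in (0, 1) on `|FC - 1|` (default 0.5).
#' @return The surviving rows, same columns as the input.
#' @export
fc_filter <- function(records, fc_threshold = 0.5) {
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1L ||
      fc_threshold <= 0 || fc_threshold >= 1) {
    abort("fc_threshold must lie in (0, 1).", class = "mirsubtype_parameter_error")
  }
  records[abs(records$fold_change - 1) > fc_threshold, , drop = FALSE]
}

#' Direction counts among significant records
#'
#' Partitions records by direction of change. If a `significant` column
#' is present only significant records are counted; otherwise all rows
#' count (so the function also works on pre-filtered record lists).
#'
#' @param records Tibble with `fold_change` (and optionally
#'   `significant`) columns.
#' @return One-row tibble with `n_increased`, `n_decreased`.
#' @export
direction_counts <- function(records) {
  records <- tibble::as_tibble(records)
  if ("significant" %in% names(records)) {
    records <- records[records$significant, , drop = FALSE]
  }
  tibble::tibble(n_increased = sum(records$fold_change > 1),
                 n_decreased = sum(records$fold_change <= 1))
}

#' @export
print.mirna_screen <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<mirna_screen> %s (%d vs %d): %d miRNAs tested, %d significant at alpha=%g (B=%d%s), %d pass |FC-1|>%g\n",
              g$contrast, g$n_positive, g$n_negative, g$n_tested,
              g$n_significant, g$alpha, g$n_permutations,
              if (g$exact_permutations) ", exact" else "",
              g$n_pass_fc_filter, g$fc_threshold))
  NextMethod()
}

#' Tidy a screen result
#'
#' `tidy()` returns the per-miRNA records as a plain tibble; `glance()`
#' returns a one-row summary with the screen parameters and counts.
#'
#' @param x A `mirna_screen`.
#' @param ... Unused.
#' @export
tidy.mirna_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mirna_screen")
  tibble::as_tibble(out)
}

#' @rdname tidy.mirna_screen
#' @export
glance.mirna_screen <- function(x, ...) {
  sig <- x[x$significant, , drop = FALSE]
  tibble::tibble(
    contrast = attr(x, "contrast_name"),
    n_positive = attr(x, "n_positive"),
    n_negative = attr(x, "n_negative"),
    n_tested = nrow(x),
    n_significant = nrow(sig),
    n_increased = sum(sig$fold_change > 1),
    n_decreased = sum(sig$fold_change <= 1),
    n_pass_fc_filter = sum(x$passes_fc_filter),
    alpha = attr(x, "alpha"),
    n_permutations = attr(x, "n_permutations"),
    exact_permutations = attr(x, "exact_permutations"),
    fc_threshold = attr(x, "fc_threshold"),
    seed = attr(x, "seed"))
}
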