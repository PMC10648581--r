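# Multi-miRNA one-vs-rest subtype classifiers: sequential forward
# selection scored by repeat-averaged stratified cross-validated AUC.

#' ROC AUC (Mann-Whitney probability)
#'
#' Fraction of (positive, negative) pairs where the positive scores
#' higher, ties counted 0.5. Equivalent to the area under the ROC curve
#' and invariant under strictly increasing transforms of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    abort("scores and labels must have the same length.")
  }
  if (anyNA(scores) || anyNA(labels)) abort("scores and labels must be complete.")
  if (all(labels == 1L) || all(labels == 0L)) {
    abort("AUC is undefined with a single class.",
          class = "mirsubtype_auc_error")
  }
  cpp_auc(as.numeric(scores), labels)
}

#' Fit a ridge-penalized logistic scorer
#'
#' Fits a logistic model of membership in the contrast's positive group
#' on standardized log2 expression of the given features, with an L2
#' penalty (intercept unpenalized) solved by IRLS. The returned scorer is
#' deterministic and scores on the log-odds (linear) scale; its
#' standardization parameters are learned from the supplied (training)
#' data only. A constant feature gets weight 0 with a warning.
#'
#' @inheritParams fold_change
#' @param features Character vector of miRNA ids to use as predictors.
#' @param regularization L2 penalty on standardized coefficients
#'   (default 1).
#' @return A `linear_scorer`: weights, intercept, and standardization
#'   parameters; use [predict()] to score samples of a `mirna_expr`.
#' @export
fit_linear_scorer <- function(expr, contrast, features, regularization = 1.0) {
  assert_scalar_number(regularization, "regularization", min = 1e-12)
  d <- contrast_design(expr, contrast)
  missing_feats <- setdiff(features, rownames(d$x))
  if (length(missing_feats)) {
    abort(sprintf("Feature(s) absent from expression matrix: %s",
                  paste(missing_feats, collapse = ", ")),
          class = "mirsubtype_validation_error")
  }
  X <- t(d$x[features, , drop = FALSE])
  constant <- apply(X, 2L, function(v) stats::sd(v) < 1e-12)
  if (any(constant)) {
    warn(sprintf("Constant feature(s) get weight 0: %s",
                 paste(features[constant], collapse = ", ")))
  }
  fit <- cpp_ridge_fit(X, as.numeric(d$y), regularization)
  structure(list(features = features,
                 weights = stats::setNames(as.numeric(fit$weights), features),
                 intercept = as.numeric(fit$intercept),
                 contrast_name = contrast$name,
                 regularization = regularization),
            class = "linear_scorer")
}

#' @export
print.linear_scorer <- function(x, ...) {
  cat(sprintf("<linear_scorer> %s: %d feature(s), lambda=%g\n",
              x$contrast_name, length(x$features), x$regularization))
  invisible(x)
}

#' @export
#' @rdname fit_linear_scorer
#' @param object A `linear_scorer`.
#' @param ... Unused.
predict.linear_scorer <- function(object, expr, ...) {
  m <- wide_to_matrix(expr)
  X <- t(m[object$features, , drop = FALSE])
  drop(object$intercept + X %*% object$weights)
}

#' Configure selection and cross-validation
#'
#' @param n_folds Folds of the stratified cross-validation (default 5;
#'   small enough that the smallest subtype groups keep a positive in
#'   every fold).
#' @param n_repeats Independent fold partitions averaged per criterion
#'   evaluation (default 50).
#' @param max_features Panel size cap (default 10).
#' @param min_improvement Minimum gain in repeat-averaged CV AUC to
#'   accept another feature (default 0.005 AUC units).
#' @param regularization L2 penalty of the base scorer (default 1).
#' @param seed Integer seed; all fold randomness derives from it.
#' @return An `sfs_config` list.
#' @export
sfs_config <- function(n_folds = 5, n_repeats = 50, max_features = 10,
                       min_improvement = 0.005, regularization = 1.0,
                       seed = 1L) {
  if (n_folds < 2) abort("n_folds must be at least 2.", class = "mirsubtype_config_error")
  if (n_repeats < 1) abort("n_repeats must be at least 1.", class = "mirsubtype_config_error")
  if (max_features < 1) abort("max_features must be at least 1.", class = "mirsubtype_config_error")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 max_features = as.integer(max_features),
                 min_improvement = min_improvement,
                 regularization = regularization,
                 seed = as.integer(seed)),
            class = "sfs_config")
}

# Stratified fold labels (1..k) for one partition seed: within each
# class, shuffle and deal folds round-robin.
make_fold_ids <- function(y, k, seed) {
  if (min(sum(y == 1), sum(y == 0)) < k) {
    abort(sprintf("Smallest class (%d) has fewer members than n_folds = %d; use a smaller n_folds.",
                  min(sum(y == 1), sum(y == 0)), k),
          class = "mirsubtype_fold_error")
  }
  ids <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      ids[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  ids
}

# n x R matrix of fold labels for R repeats, seeds derived from a label path.
fold_id_matrix <- function(y, k, n_repeats, seed, ...) {
  ids <- vapply(seq_len(n_repeats),
                function(r) make_fold_ids(y, k, derive_seed(seed, ..., r)),
                integer(length(y)))
  storage.mode(ids) <- "integer"
  ids
}

#' Cross-validated AUC of a feature panel
#'
#' One repeat of stratified `n_folds` cross-validation: the partition is
#' drawn from `repeat_seed`, a ridge-logistic scorer is trained on each
#' fold's complement (standardization learned on training folds only),
#' held-out scores are pooled across folds, and a single AUC is computed
#' on the pooled scores. Deterministic given `repeat_seed`.
#'
#' @inheritParams fit_linear_scorer
#' @param config An [sfs_config()].
#' @param repeat_seed Integer seed for this repeat's fold partition.
#' @return Scalar AUC.
#' @export
cv_auc <- function(expr, contrast, features, config = sfs_config(),
                   repeat_seed = config$seed) {
  d <- contrast_design(expr, contrast)
  X <- t(d$x[features, , drop = FALSE])
  foldids <- matrix(make_fold_ids(d$y, config$n_folds, repeat_seed), ncol = 1L)
  as.numeric(cpp_cv_panel_aucs(X, as.numeric(d$y), foldids, config$regularization))
}

cv_repeat_aucs <- function(d, features_idx, config, foldids) {
  X <- t(d$x[features_idx, , drop = FALSE])
  as.numeric(cpp_cv_panel_aucs(X, as.numeric(d$y), foldids, config$regularization))
}

#' Sequential forward selection of a miRNA panel
#'
#' Greedy panel construction: starting from the empty set, each step
#' evaluates every remaining candidate's repeat-averaged cross-validated
#' AUC when added to the current panel (all candidates share the step's
#' `n_repeats` fold partitions, derived from `config$seed`), and adds the
#' best candidate if it improves the criterion by at least
#' `min_improvement` over the current value (baseline 0.5). Selection
#' stops otherwise, or at `max_features`. Ties break toward the earlier
#' candidate in `candidates` for reproducibility.
#'
#' The reported `repeat_aucs`/`mean_auc` are recomputed for the selected
#' panel on `n_repeats` fresh fold partitions disjoint from those used
#' during selection, so the headline AUC is not the selection-time
#' optimum. If no candidate ever clears the baseline, the single best
#' candidate is returned with a warning rather than an empty model.
#'
#' @inheritParams fit_linear_scorer
#' @param candidates Candidate miRNA ids (default: all miRNAs in
#'   `expr`).
#' @param config An [sfs_config()].
#' @return A `subtype_model`: selected panel (in selection order),
#'   per-repeat and mean evaluation AUC, selection trace, pooled held-out
#'   scores for ROC plotting, and the full-data scorer.
#' @export
sequential_forward_select <- function(expr, contrast,
                                      candidates = NULL,
                                      config = sfs_config()) {
  d <- contrast_design(expr, contrast)
  candidates <- candidates %||% rownames(d$x)
  missing_cand <- setdiff(candidates, rownames(d$x))
  if (length(missing_cand)) {
    abort(sprintf("Candidate(s) absent from expression matrix: %s",
                  paste(missing_cand, collapse = ", ")),
          class = "mirsubtype_validation_error")
  }
  if (!length(candidates)) abort("Need at least one candidate.",
                                 class = "mirsubtype_config_error")
  Xall <- t(d$x[candidates, , drop = FALSE])
  y <- as.numeric(d$y)

  selected <- integer(0)              # 0-based indices into candidates
  remaining <- seq_along(candidates) - 1L
  criterion <- 0.5
  trace <- list()
  first_step <- NULL

  for (step in seq_len(config$max_features)) {
    if (!length(remaining)) break
    foldids <- fold_id_matrix(d$y, config$n_folds, config$n_repeats,
                              config$seed, "select", step)
    aucs <- as.numeric(cpp_candidate_mean_aucs(
      Xall, y, as.integer(selected), as.integer(remaining),
      foldids, config$regularization))
    best <- which.max(aucs)           # ties -> earliest candidate index
    if (step == 1L) first_step <- list(idx = remaining[best], auc = aucs[best])
    if (aucs[best] < criterion + config$min_improvement) break
    criterion <- aucs[best]
    selected <- c(selected, remaining[best])
    trace[[step]] <- tibble::tibble(
      step = step, mirna_id = candidates[remaining[best] + 1L],
      criterion_auc = criterion)
    remaining <- remaining[-best]
  }

  if (!length(selected)) {
    warn(sprintf("No candidate improved the cross-validated AUC over the 0.5 baseline for '%s'; returning the single best candidate.",
                 contrast$name))
    selected <- first_step$idx
    trace[[1L]] <- tibble::tibble(step = 1L,
                                  mirna_id = candidates[selected + 1L],
                                  criterion_auc = first_step$auc)
  }

  panel <- candidates[selected + 1L]
  # evaluation on fold seeds disjoint from every selection seed
  eval_folds <- fold_id_matrix(d$y, config$n_folds, config$n_repeats,
                               config$seed, "evaluate")
  repeat_aucs <- cv_repeat_aucs(d, panel, config, eval_folds)
  scores <- as.numeric(cpp_cv_scores(t(d$x[panel, , drop = FALSE]), y,
                                     eval_folds[, 1L], config$regularization))

  structure(list(contrast_name = contrast$name,
                 selected_mirnas = panel,
                 mean_auc = mean(repeat_aucs),
                 repeat_aucs = repeat_aucs,
                 selection_trace = dplyr::bind_rows(trace),
                 cv_scores = tibble::tibble(
                   sample_id = c(contrast$positive_ids, contrast$negative_ids),
                   score = scores, label = d$y),
                 scorer = fit_linear_scorer(expr, contrast, panel,
                                            config$regularization),
                 n_positive = sum(d$y), n_negative = sum(d$y == 0),
                 config = config),
            class = "subtype_model")
}

#' Build one-vs-rest subtype models for several targets
#'
#' Runs [sequential_forward_select()] once per `(variable, level)`
#' target. A target whose contrast cannot be formed (too few samples)
#' is skipped with a warning; the remaining targets still run. The
#' default targets are the three subtypes the package builds models for:
#' MMR-deficient, p53-abnormal, and CTNNB1-mutated tumors.
#'
#' @inheritParams sequential_forward_select
#' @param ann Sample annotation tibble.
#' @param targets Tibble with columns `variable`, `level`.
#' @return Named list of `subtype_model` objects (one per successful
#'   target).
#' @export
build_subtype_models <- function(expr, ann,
                                 targets = default_model_targets(),
                                 candidates = NULL,
                                 config = sfs_config()) {
  targets <- tibble::as_tibble(targets)
  models <- list()
  for (i in seq_len(nrow(targets))) {
    variable <- targets$variable[i]; level <- targets$level[i]
    name <- paste0(variable, ":", level)
    res <- tryCatch({
      contrast <- make_contrast(ann, variable, level,
                                samples = names(expr)[-1L])
      sequential_forward_select(expr, contrast, candidates, config)
    }, mirsubtype_contrast_error = function(e) {
      warn(sprintf("Skipping target %s: %s", name, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) models[[name]] <- res
  }
  models
}

#' @rdname build_subtype_models
#' @export
default_model_targets <- function() {
  tibble::tibble(variable = c("molecular", "molecular", "ctnnb1"),
                 level = c("MMRd", "p53abn", "mutated"))
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("<subtype_model> %s: %d-miRNA panel, mean CV AUC %.3f over %d repeats (%d-fold)\n",
              x$contrast_name, length(x$selected_mirnas), x$mean_auc,
              length(x$repeat_aucs), x$config$n_folds))
  cat("  panel:", paste(x$selected_mirnas, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fitted subtype model
#'
#' `tidy()` returns one row per selected miRNA: selection step, the
#' criterion (repeat-averaged selection CV AUC) when it was added, and
#' its weight in the full-data scorer. `glance()` returns a one-row model
#' summary.
#'
#' @param x A `subtype_model`.
#' @param ... Unused.
#' @export
tidy.subtype_model <- function(x, ...) {
  dplyr::mutate(x$selection_trace,
                weight = unname(x$scorer$weights[x$selection_trace$mirna_id]))
}

#' @rdname tidy.subtype_model
#' @export
glance.subtype_model <- function(x, ...) {
  tibble::tibble(contrast = x$contrast_name,
                 n_features = length(x$selected_mirnas),
                 mean_auc = x$mean_auc,
                 sd_auc = stats::sd(x$repeat_aucs),
                 n_repeats = length(x$repeat_aucs),
                 n_folds = x$config$n_folds,
                 n_positive = x$n_positive,
                 n_negative = x$n_negative,
                 seed = x$config$seed)
}

#' ROC curve points of a model's held-out scores
#'
#' Sweeps every distinct pooled held-out score as a threshold and reports
#' the true- and false-positive rates, for Figure-style ROC plots.
#'
#' @param model A `subtype_model`.
#' @return Tibble with `threshold`, `tpr`, `fpr`, ordered from the
#'   (0, 0) to the (1, 1) corner.
#' @export
roc_points <- function(model) {
  s <- model$cv_scores$score
  y <- model$cv_scores$label
  thresholds <- c(Inf, sort(unique(s), decreasing = TRUE))
  tibble::tibble(
    threshold = thresholds,
    tpr = vapply(thresholds, function(t) mean(s[y == 1] >= t), numeric(1)),
    fpr = vapply(thresholds, function(t) mean(s[y == 0] >= t), numeric(1)))
}
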