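test_that("roc_auc equals brute-force pair counting, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4, 3, 1, 0), c(1, 1, 0, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(2, 6), c(1, 1, 1, 0, 0, 0)), 0.5)

  set.seed(12)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels), pair_count_auc(scores, labels))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), class = "mirsubtype_auc_error")
})

test_that("roc_auc is rank-invariant and complement-antisymmetric", {
  set.seed(3)
  scores <- rnorm(30)
  labels <- sample(0:1, 30, replace = TRUE, prob = c(0.6, 0.4))
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)        # strictly increasing map
  expect_equal(roc_auc(rank(scores), labels), a)
  expect_equal(roc_auc(-scores, labels), 1 - a)        # tie-free complement
})

test_that("the ridge scorer separates a strong noiseless feature", {
  eff <- tibble::tibble(variable = "histology", level = "serous",
                        mirna_id = "miR-x", fold_change = 8)
  co <- generate_cohort(small_cohort_config(effects = eff, noise_sd = 0))
  expr <- normalize_ct(co$ct)
  ctr <- make_contrast(co$annotations, "histology", "serous")
  scorer <- fit_linear_scorer(expr, ctr, "miR-x")
  scores <- predict(scorer, expr)
  y <- names(scores) %in% ctr$positive_ids
  expect_equal(roc_auc(scores[c(ctr$positive_ids, ctr$negative_ids)],
                       c(rep(1, 6), rep(0, 30))), 1.0)
  expect_gt(scorer$weights[["miR-x"]], 0)
})

test_that("increased-expression features get positive weights across seeds", {
  eff <- tibble::tibble(variable = "histology", level = "endometrioid",
                        mirna_id = "miR-x", fold_change = 4)
  signs <- vapply(1:25, function(s) {
    co <- generate_cohort(small_cohort_config(effects = eff, seed = s))
    expr <- normalize_ct(co$ct)
    ctr <- make_contrast(co$annotations, "histology", "endometrioid")
    sign(fit_linear_scorer(expr, ctr, "miR-x")$weights[["miR-x"]])
  }, numeric(1))
  expect_true(all(signs > 0))
})

test_that("a constant feature is tolerated with weight zero", {
  expr <- as_expr(rbind("flat" = rep(3, 12), "ok" = c(rnorm(6, 2), rnorm(6))))
  ctr <- split_contrast(expr, 6)
  expect_warning(scorer <- fit_linear_scorer(expr, ctr, c("flat", "ok")),
                 "flat")
  expect_equal(unname(scorer$weights["flat"]), 0, tolerance = 1e-8)
})

test_that("ridge logistic agrees with glmnet on a standardized two-feature fit", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  n <- 80
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * X[, "a"] - 0.5))
  expr <- as_expr(t(X))
  ids <- names(expr)[-1L]
  ctr <- new_contrast("g", ids[y == 1], ids[y == 0])
  scorer <- fit_linear_scorer(expr, ctr, c("a", "b"), regularization = 2)
  # glmnet penalizes (lambda/2)*n implicit scaling: lambda_glmnet = reg / n
  g <- glmnet::glmnet(scale(X), y[order(match(ids, ids))], family = "binomial",
                      alpha = 0, lambda = 2 / n, standardize = FALSE,
                      thresh = 1e-12)
  w_glmnet <- as.numeric(g$beta)
  w_ours <- scorer$weights * apply(X, 2, sd)  # back to standardized scale
  # order of samples differs between the two fits only by permutation
  expect_equal(unname(w_ours), w_glmnet, tolerance = 0.02)
})

test_that("cross-validated AUC is deterministic and honest on pure noise", {
  co <- generate_cohort(small_cohort_config(seed = 12))
  expr <- normalize_ct(co$ct)
  ctr <- make_contrast(co$annotations, "histology", "endometrioid")
  cfg <- sfs_config(n_folds = 4, seed = 9)
  a1 <- cv_auc(expr, ctr, c("miR-sim-001", "miR-sim-002"), cfg, repeat_seed = 11)
  a2 <- cv_auc(expr, ctr, c("miR-sim-001", "miR-sim-002"), cfg, repeat_seed = 11)
  expect_identical(a1, a2)
  expect_gt(a1, 0.25); expect_lt(a1, 0.75)  # null band for one repeat

  expect_error(cv_auc(expr, make_contrast(co$annotations, "histology", "dedifferentiated"),
                      "miR-sim-001", sfs_config(n_folds = 5)),
               class = "mirsubtype_fold_error")
})

test_that("a strongly informative feature dominates cross-validation", {
  eff <- tibble::tibble(variable = "molecular", level = "MMRd",
                        mirna_id = "miR-hot", fold_change = 8)
  co <- generate_cohort(cohort_config(
    n_mirnas = 30, n_spikeins = 6,
    histology_sizes = c(endometrioid = 60, serous = 42),
    molecular_sizes = c(MMRd = 48, p53wt = 54),
    ctnnb1_n_mutated = 5, n_sequenced = 60,
    effects = eff, seed = 3))
  expr <- normalize_ct(co$ct)
  ctr <- make_contrast(co$annotations, "molecular", "MMRd")
  auc <- mean(vapply(1:5, function(r)
    cv_auc(expr, ctr, "miR-hot", sfs_config(), repeat_seed = r), numeric(1)))
  expect_gt(auc, 0.9)
})

test_that("forward selection finds planted panels and keeps its contracts", {
  eff <- tibble::tibble(variable = "molecular", level = "MMRd",
                        mirna_id = c("miR-a1", "miR-a2", "miR-a3"),
                        fold_change = c(4, 4, 0.25))
  co <- generate_cohort(cohort_config(
    n_mirnas = 60, n_spikeins = 6,
    histology_sizes = c(endometrioid = 60, serous = 42),
    molecular_sizes = c(MMRd = 48, p53wt = 54),
    ctnnb1_n_mutated = 5, n_sequenced = 60,
    effects = eff, seed = 21))
  expr <- normalize_ct(co$ct)
  ctr <- make_contrast(co$annotations, "molecular", "MMRd")
  cfg <- sfs_config(n_repeats = 10, seed = 5)
  model <- sequential_forward_select(expr, ctr, config = cfg)

  expect_true(all(c("miR-a1", "miR-a2", "miR-a3") %in% model$selected_mirnas))
  expect_lte(length(model$selected_mirnas), cfg$max_features)
  expect_false(anyDuplicated(model$selected_mirnas) > 0)
  expect_true(all(diff(model$selection_trace$criterion_auc) >= 0))
  expect_equal(model$mean_auc, mean(model$repeat_aucs))
  expect_length(model$repeat_aucs, cfg$n_repeats)

  # the multi-miRNA model beats each of its single features (held-out AUC)
  singles <- vapply(model$selected_mirnas[1:3], function(f)
    mean(vapply(1:5, function(r) cv_auc(expr, ctr, f, cfg, repeat_seed = 1000 + r),
                numeric(1))), numeric(1))
  expect_gt(model$mean_auc, max(singles))

  # byte-identical rerun
  model2 <- sequential_forward_select(expr, ctr, config = cfg)
  expect_identical(model_json(model), model_json(model2))
})

test_that("selection falls back to the single best candidate on hopeless input", {
  expr <- as_expr(rbind("flat1" = rep(1, 20), "flat2" = rep(2, 20)))
  ctr <- split_contrast(expr, 10)
  # also warns about the constant feature when refitting the fallback panel
  suppressWarnings(expect_warning(
    model <- sequential_forward_select(expr, ctr,
                                       config = sfs_config(n_repeats = 3, n_folds = 2)),
    "baseline"))
  expect_length(model$selected_mirnas, 1L)
  expect_equal(model$mean_auc, 0.5, tolerance = 1e-9)
})

test_that("build_subtype_models runs per target and skips impossible ones", {
  eff <- subtype_effect_catalogue("molecular", "p53abn")
  co <- generate_cohort(cohort_config(effects = eff, seed = 6))
  expr <- normalize_ct(co$ct)
  targets <- tibble::tibble(variable = c("molecular", "histology"),
                            level = c("p53abn", "serous"))
  cfg <- sfs_config(n_repeats = 5, max_features = 3, seed = 2)
  models <- build_subtype_models(expr, co$annotations, targets = targets,
                                 config = cfg)
  expect_named(models, c("molecular:p53abn", "histology:serous"))
  expect_s3_class(models[["molecular:p53abn"]], "subtype_model")

  expect_equal(build_subtype_models(expr, co$annotations,
                                    targets = targets[0, ], config = cfg),
               list() , ignore_attr = TRUE)
})

test_that("tidy, glance and roc_points expose the fitted model coherently", {
  eff <- tibble::tibble(variable = "histology", level = "endometrioid",
                        mirna_id = "miR-x", fold_change = 6)
  co <- generate_cohort(small_cohort_config(effects = eff))
  expr <- normalize_ct(co$ct)
  ctr <- make_contrast(co$annotations, "histology", "endometrioid")
  model <- sequential_forward_select(expr, ctr,
                                     config = sfs_config(n_repeats = 4, n_folds = 4,
                                                         max_features = 2, seed = 3))
  td <- tidy(model)
  expect_equal(td$mirna_id, model$selected_mirnas)
  g <- glance(model)
  expect_equal(g$n_features, length(model$selected_mirnas))
  expect_equal(g$mean_auc, model$mean_auc)

  pts <- roc_points(model)
  expect_equal(pts$tpr[1], 0); expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1); expect_equal(pts$fpr[nrow(pts)], 1)
  expect_true(all(diff(pts$tpr) >= 0) && all(diff(pts$fpr) >= 0))
})
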