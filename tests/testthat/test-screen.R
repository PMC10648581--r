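test_that("pooled-variance t matches the closed form and stats::t.test", {
  expr <- as_expr(rbind("m1" = c(1, 2, 3, 2, 3, 4)))
  ctr <- split_contrast(expr, 3)
  expect_equal(student_t(expr, ctr, "m1"), -1.224745, tolerance = 1e-6)

  set.seed(21)
  v <- rnorm(12)
  e2 <- as_expr(rbind("m1" = v))
  c2 <- split_contrast(e2, 5)
  ref <- unname(stats::t.test(v[1:5], v[6:12], var.equal = TRUE)$statistic)
  expect_equal(student_t(e2, c2, "m1"), ref, tolerance = 1e-12)

  # antisymmetry: swapping group roles flips the sign only
  swapped <- new_contrast("swap", c2$negative_ids, c2$positive_ids)
  expect_equal(student_t(e2, swapped, "m1"), -ref, tolerance = 1e-12)

  # degenerate pooled variance
  e3 <- as_expr(rbind("m1" = rep(1, 6), "m2" = c(1, 1, 1, 2, 2, 2)))
  c3 <- split_contrast(e3, 3)
  expect_equal(student_t(e3, c3, "m1"), 0)
  expect_identical(student_t(e3, c3, "m2"), -Inf)
})

test_that("fold change is the ratio of geometric means", {
  expr <- as_expr(rbind("null" = c(5, 6, 7, 5, 6, 7),
                        "up" = c(6, 7, 8, 5, 6, 7)))
  ctr <- split_contrast(expr, 3)
  expect_equal(fold_change(expr, ctr, "null"), 1.0)
  expect_equal(fold_change(expr, ctr, "up"), 2.0)
  expect_error(fold_change(expr, ctr, "absent"),
               class = "mirsubtype_validation_error")
})

test_that("sampled fold-change estimates stay near a planted 2x effect", {
  eff <- tibble::tibble(variable = "histology", level = "endometrioid",
                        mirna_id = "miR-x", fold_change = 2)
  est <- vapply(1:50, function(s) {
    co <- generate_cohort(cohort_config(
      n_mirnas = 10, n_spikeins = 4,
      histology_sizes = c(endometrioid = 30, serous = 30),
      molecular_sizes = c(MMRd = 20, p53wt = 20),
      ctnnb1_n_mutated = 4, n_sequenced = 30,
      effects = eff, noise_sd = 0.5, seed = s))
    expr <- normalize_ct(co$ct)
    fold_change(expr, make_contrast(co$annotations, "histology", "endometrioid"),
                "miR-x")
  }, numeric(1))
  expect_equal(mean(est), 2.0, tolerance = 0.1)
  expect_true(all(est > 1.5 & est < 2.7))
})

test_that("permutation p equals the exhaustive enumeration oracle", {
  set.seed(77)
  for (n1 in c(3, 4)) {
    v <- rnorm(n1 + 3)
    expr <- as_expr(rbind("m1" = v))
    ctr <- split_contrast(expr, n1)
    p <- permutation_p(expr, ctr, "m1", B = 1000, seed = 1)
    expect_equal(p, enumerate_perm_p(v, n1), tolerance = 1e-12)
  }
})

test_that("permutation p-values are conservative, reproducible, and never zero", {
  set.seed(30)
  v <- c(rnorm(15), rnorm(15, mean = 6))  # extreme separation
  expr <- as_expr(rbind("m1" = v))
  ctr <- split_contrast(expr, 15)
  p1 <- permutation_p(expr, ctr, "m1", B = 199, seed = 9)
  p2 <- permutation_p(expr, ctr, "m1", B = 199, seed = 9)
  expect_identical(p1, p2)
  expect_equal(p1, 1 / 200)  # floor of the (b+1)/(B+1) estimator

  tied <- as_expr(rbind("m1" = rep(c(1, 2, 3), 4)))
  expect_equal(permutation_p(tied, split_contrast(tied, 6), "m1", B = 500, seed = 2), 1.0)

  expect_error(permutation_p(expr, ctr, "m1", B = 0),
               class = "mirsubtype_parameter_error")
})

test_that("the screen flags exactly the planted miRNA in the noiseless limit", {
  eff <- tibble::tibble(variable = "histology", level = "serous",
                        mirna_id = "miR-x", fold_change = 4)
  co <- generate_cohort(small_cohort_config(effects = eff, noise_sd = 0))
  expr <- normalize_ct(co$ct)
  ctr <- make_contrast(co$annotations, "histology", "serous")
  scr <- run_screen(expr, ctr, B = 500, seed = 3)
  expect_identical(scr$mirna_id[scr$significant], "miR-x")
  expect_identical(scr$mirna_id[scr$passes_fc_filter], "miR-x")

  none <- run_screen(expr, ctr, alpha = 0, B = 200, seed = 3)
  expect_equal(sum(none$significant), 0L)
})

test_that("fold-change filter keeps |FC - 1| > threshold, strictly", {
  nsmp <- tibble::tibble(fold_change = c(2.07, 1.51, 1.47, 1.45, 1.35, 0.34, 0.52, 0.68))
  kept <- fc_filter(nsmp)
  expect_equal(sort(kept$fold_change), sort(c(2.07, 1.51, 0.34)))

  boundary <- tibble::tibble(fold_change = c(1.5, 0.5, 1.5000001, 0.4999999))
  expect_equal(fc_filter(boundary)$fold_change, c(1.5000001, 0.4999999))

  expect_error(fc_filter(nsmp, fc_threshold = 1.2),
               class = "mirsubtype_parameter_error")
  expect_error(fc_filter(nsmp, fc_threshold = 0),
               class = "mirsubtype_parameter_error")
})

test_that("direction counts partition significant records by direction", {
  expect_equal(direction_counts(tibble::tibble(fold_change = double())),
               tibble::tibble(n_increased = 0L, n_decreased = 0L))
  expect_equal(direction_counts(tibble::tibble(fold_change = c(2, 0.5, 3))),
               tibble::tibble(n_increased = 2L, n_decreased = 1L))

  eff <- tibble::tibble(variable = "histology", level = "endometrioid",
                        mirna_id = sprintf("miR-e%d", 1:8),
                        fold_change = c(4, 5, 6, 8, 4, 0.25, 0.2, 0.1))
  co <- generate_cohort(small_cohort_config(effects = eff, noise_sd = 0))
  expr <- normalize_ct(co$ct)
  scr <- run_screen(expr, make_contrast(co$annotations, "histology", "endometrioid"),
                    B = 500, seed = 4)
  expect_equal(direction_counts(scr),
               tibble::tibble(n_increased = 5L, n_decreased = 3L))
})

test_that("stronger planted effects never weaken the observed t statistic", {
  t_of <- function(fc) {
    eff <- tibble::tibble(variable = "histology", level = "endometrioid",
                          mirna_id = "miR-x", fold_change = fc)
    co <- generate_cohort(small_cohort_config(effects = eff, seed = 17L))
    expr <- normalize_ct(co$ct)
    abs(student_t(expr, make_contrast(co$annotations, "histology", "endometrioid"),
                  "miR-x"))
  }
  ts <- vapply(c(1.5, 2, 4, 8, 16), t_of, numeric(1))
  expect_true(all(diff(ts) >= 0))
})

test_that("screen records are internally consistent", {
  co <- generate_cohort(cohort_config(seed = 42))
  expr <- normalize_ct(co$ct)
  scr <- run_screen(expr, make_contrast(co$annotations, "histology", "endometrioid"),
                    B = 200, seed = 6)
  expect_equal(nrow(scr), nrow(expr))
  expect_true(all(scr$perm_p >= 1 / 201 & scr$perm_p <= 1))
  expect_true(all((scr$direction == "increased") == (scr$fold_change > 1)))
  expect_true(all(fc_filter(scr)$mirna_id %in% scr$mirna_id))
  g <- glance(scr)
  expect_equal(g$n_significant, sum(scr$significant))
  expect_equal(g$n_tested, nrow(scr))
})
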