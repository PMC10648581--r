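test_that("TSV parsing flags spike-ins and round-trips losslessly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("assay_id\tS1\tS2",
               "miR-a\t25.5\t26.125",
               "miR-b\t30\tNA",
               "SPIKE_01\t20.25\t21"), path)
  ct <- read_ct_matrix(path)
  expect_s3_class(ct, "ct_matrix")
  expect_equal(nrow(ct), 3L)
  expect_equal(spike_in_ids(ct), "SPIKE_01")
  expect_true(is.na(ct$S2[ct$assay_id == "miR-b"]))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_ct_matrix(ct, out)
  back <- read_ct_matrix(out)
  expect_identical(tibble::as_tibble(back), tibble::as_tibble(ct))
})

test_that("format violations are rejected with the offending cell named", {
  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("assay_id\tS1\tS1", "miR-a\t25\t26"), dup)
  expect_error(read_ct_matrix(dup), "S1", class = "mirsubtype_format_error")

  nonnum <- file.path(dir, "nonnum.tsv")
  writeLines(c("assay_id\tS1", "miR-a\ttwenty"), nonnum)
  expect_error(read_ct_matrix(nonnum), "twenty", class = "mirsubtype_format_error")

  range <- file.path(dir, "range.tsv")
  writeLines(c("assay_id\tS1", "miR-a\t48.5"), range)
  expect_error(read_ct_matrix(range), "miR-a", class = "mirsubtype_validation_error")

  dupa <- file.path(dir, "dupa.tsv")
  writeLines(c("assay_id\tS1", "miR-a\t25", "miR-a\t26"), dupa)
  expect_error(read_ct_matrix(dupa), "miR-a", class = "mirsubtype_format_error")
})

test_that("normalization subtracts Ct from the per-sample spike-in median", {
  ct <- ct_matrix(tibble::tibble(
    assay_id = c("miR-a", "SPIKE_01", "SPIKE_02", "SPIKE_03"),
    S1 = c(15, 19, 20, 21),
    S2 = c(18, 21, 22, 23)), spike_in_ids = paste0("SPIKE_0", 1:3))
  expr <- normalize_ct(ct)
  expect_equal(expr$S1[expr$mirna_id == "miR-a"], 5)
  expect_equal(expr$S2[expr$mirna_id == "miR-a"], 4)
  expect_false(any(expr$mirna_id %in% spike_in_ids(ct)))
})

test_that("normalization is invariant under per-sample additive Ct shifts", {
  cfg <- small_cohort_config()
  co <- generate_cohort(cfg)
  base <- tibble::as_tibble(co$ct)
  shifted <- base
  shifted$EC003 <- shifted$EC003 + 1.75  # whole-sample shift, spike-ins included
  ct2 <- ct_matrix(shifted, spike_in_ids = spike_in_ids(co$ct))
  # detection limit above the shifted range so censoring stays identical
  e1 <- normalize_ct(co$ct, detection_limit = 45)
  e2 <- normalize_ct(ct2, detection_limit = 45)
  expect_equal(e2, e1, tolerance = 1e-12)
})

test_that("technical sample shifts add no between-sample variance after normalization", {
  # same biological draw with and without technical shifts: the normalized
  # between-sample SD of null miRNAs must agree closely
  sd_of <- function(shift_sd) {
    co <- generate_cohort(small_cohort_config(sample_shift_sd = shift_sd,
                                              seed = 99L))
    e <- normalize_ct(co$ct)
    m <- e[, -1L] |> as.matrix()
    mean(apply(m, 1L, sd))
  }
  expect_equal(sd_of(2), sd_of(0), tolerance = 0.05)
})

test_that("undetected handling drops high-missingness miRNAs and imputes the rest", {
  ct <- ct_matrix(tibble::tibble(
    assay_id = c("miR-mostly-missing", "miR-partial", "miR-clean", "SPIKE_01"),
    S1 = c(NA, 25, 25, 20), S2 = c(NA, 26, 25, 20),
    S3 = c(30, 39, 25, 20), S4 = c(30, 27, 25, 20)),
    spike_in_ids = "SPIKE_01")
  expr <- normalize_ct(ct, detection_limit = 38, max_missing_frac = 0.25)
  # 2/4 missing > 25% -> dropped; Ct 39 >= limit -> undetected -> imputed
  expect_setequal(expr$mirna_id, c("miR-partial", "miR-clean"))
  partial <- unlist(expr[expr$mirna_id == "miR-partial", -1L])
  expect_equal(unname(partial["S3"]), min(partial[c("S1", "S2", "S4")]) - 1)
  expect_true(all(is.finite(as.matrix(expr[, -1L]))))
})

test_that("a sample without usable spike-in Ct is reported by name", {
  ct <- ct_matrix(tibble::tibble(
    assay_id = c("miR-a", "SPIKE_01"),
    GOOD = c(25, 20), BAD = c(25, NA)), spike_in_ids = "SPIKE_01")
  expect_error(normalize_ct(ct), "BAD", class = "mirsubtype_validation_error")
})
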