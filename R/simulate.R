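#' Configure a synthetic RT-qPCR cohort
#'
#' Describes a simulated tumor cohort in the Ct domain: group sizes,
#' planted subtype-specific fold changes, log-normal biological noise
#' (Gaussian in log2/Ct units, matching delta-Ct behavior), per-sample
#' technical shifts, and detection-limit censoring. The defaults mirror
#' the endometrial-carcinoma study design the package targets: a
#' 352-miRNA panel with 32 spike-in controls, 119 tumors split
#' 89/8/13/9 across histological subtypes, 102 of them molecularly
#' subtyped 48/8/35/11, 19 CTNNB1-mutated among 92 sequenced, and the
#' published fold-change catalogue as the planted-effect set.
#'
#' @param n_mirnas Number of miRNA assays on the panel (default 352).
#' @param n_spikeins Number of synthetic spike-in control assays
#'   (default 32).
#' @param histology_sizes Named counts per histological subtype; the sum
#'   is the cohort size.
#' @param molecular_sizes Named counts per molecular subtype, assigned to
#'   a random subset of samples; the remainder stay `"unknown"`.
#' @param ctnnb1_n_mutated Number of CTNNB1-mutated samples (default 19,
#'   of which ~17/19 are placed in endometrioid tumors).
#' @param n_sequenced Number of samples with a known CTNNB1 call
#'   (default 92); the rest are `"unknown"`.
#' @param effects Planted effects: tibble with columns `variable`,
#'   `level`, `mirna_id`, `fold_change` (linear ratio, target group vs
#'   rest). Default [subtype_effect_catalogue()]. `NULL` for a null
#'   cohort.
#' @param baseline_ct_mean Mean miRNA quantification cycle (default 28).
#' @param baseline_ct_sd Between-miRNA SD of the baseline Ct (default 2).
#' @param noise_sd Between-sample within-group biological SD, log2 units
#'   (default 1).
#' @param sample_shift_sd SD of the per-sample additive technical Ct
#'   shift applied to every assay of a sample (default 1).
#' @param spikein_ct Quantification cycle around which spike-in controls
#'   read out (default 20).
#' @param detection_limit Ct above which a well is emitted as missing
#'   (default 38).
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_mirnas = 352,
                          n_spikeins = 32,
                          histology_sizes = c(endometrioid = 89, serous = 8,
                                              clear_cell = 13, dedifferentiated = 9),
                          molecular_sizes = c(MMRd = 48, POLE = 8,
                                              p53wt = 35, p53abn = 11),
                          ctnnb1_n_mutated = 19,
                          n_sequenced = 92,
                          effects = subtype_effect_catalogue(),
                          baseline_ct_mean = 28,
                          baseline_ct_sd = 2,
                          noise_sd = 1.0,
                          sample_shift_sd = 1.0,
                          spikein_ct = 20,
                          detection_limit = 38,
                          seed = 1L) {
  cfg <- list(n_mirnas = n_mirnas, n_spikeins = n_spikeins,
              histology_sizes = histology_sizes,
              molecular_sizes = molecular_sizes,
              ctnnb1_n_mutated = ctnnb1_n_mutated,
              n_sequenced = n_sequenced,
              effects = if (is.null(effects)) empty_effects() else tibble::as_tibble(effects),
              baseline_ct_mean = baseline_ct_mean,
              baseline_ct_sd = baseline_ct_sd,
              noise_sd = noise_sd,
              sample_shift_sd = sample_shift_sd,
              spikein_ct = spikein_ct,
              detection_limit = detection_limit,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

empty_effects <- function() {
  tibble::tibble(variable = character(), level = character(),
                 mirna_id = character(), fold_change = double())
}

validate_cohort_config <- function(cfg) {
  assert_scalar_number(cfg$n_mirnas, "n_mirnas", 1)
  assert_scalar_number(cfg$n_spikeins, "n_spikeins", 1)
  if (is.null(names(cfg$histology_sizes)) ||
      !all(names(cfg$histology_sizes) %in% HISTOLOGY_LEVELS)) {
    abort("histology_sizes must be named with histological subtype levels.",
          class = "mirsubtype_config_error")
  }
  if (any(cfg$histology_sizes < 0) || sum(cfg$histology_sizes) < 4) {
    abort("histology_sizes must be non-negative and sum to a usable cohort size.",
          class = "mirsubtype_config_error")
  }
  if (is.null(names(cfg$molecular_sizes)) ||
      !all(names(cfg$molecular_sizes) %in% MOLECULAR_LEVELS)) {
    abort("molecular_sizes must be named with molecular subtype levels.",
          class = "mirsubtype_config_error")
  }
  n <- sum(cfg$histology_sizes)
  if (sum(cfg$molecular_sizes) > n) {
    abort("molecular_sizes cannot exceed the cohort size.",
          class = "mirsubtype_config_error")
  }
  if (cfg$ctnnb1_n_mutated > cfg$n_sequenced || cfg$n_sequenced > n) {
    abort("Need ctnnb1_n_mutated <= n_sequenced <= cohort size.",
          class = "mirsubtype_config_error")
  }
  eff <- cfg$effects
  needed <- c("variable", "level", "mirna_id", "fold_change")
  if (!all(needed %in% names(eff))) {
    abort("effects must have columns variable, level, mirna_id, fold_change.",
          class = "mirsubtype_config_error")
  }
  if (nrow(eff)) {
    if (any(eff$fold_change <= 0)) {
      abort("Planted fold changes must be positive linear ratios.",
            class = "mirsubtype_config_error")
    }
    if (anyDuplicated(eff[c("variable", "level", "mirna_id")])) {
      abort("Duplicate planted effect for the same (mirna, variable, level).",
            class = "mirsubtype_config_error")
    }
    ok_level <- (eff$variable == "histology" & eff$level %in% HISTOLOGY_LEVELS) |
      (eff$variable == "molecular" & eff$level %in% MOLECULAR_LEVELS) |
      (eff$variable == "ctnnb1" & eff$level %in% CTNNB1_LEVELS)
    if (!all(ok_level)) {
      bad <- eff[!ok_level, ]
      abort(sprintf("Planted effect references unknown level: %s=%s",
                    bad$variable[1L], bad$level[1L]),
            class = "mirsubtype_config_error")
    }
    if (length(unique(eff$mirna_id)) > cfg$n_mirnas) {
      abort("More distinct effect miRNAs than panel slots (n_mirnas).",
            class = "mirsubtype_config_error")
    }
  }
  if (cfg$noise_sd < 0 || cfg$baseline_ct_sd < 0 || cfg$sample_shift_sd < 0) {
    abort("Noise SDs must be non-negative.", class = "mirsubtype_config_error")
  }
  invisible(cfg)
}

#' Generate a synthetic cohort in the Ct domain
#'
#' Simulates the full measurement chain so every downstream stage has a
#' ground-truth oracle. Each miRNA gets a baseline log2 level relative to
#' the spike-in reference; samples belonging to a planted effect's group
#' receive an additional `log2(fold_change)`; Gaussian noise (`noise_sd`)
#' is added per sample; the Ct read-out is
#' `spikein_ct - expression + shift(sample)` with a per-sample technical
#' shift, and wells beyond `detection_limit` are emitted as missing.
#' Identical config (seed included) reproduces the output bit-exactly.
#'
#' @param config A [cohort_config()].
#' @return A `mirna_cohort` list: `ct` ([ct_matrix()] including spike-in
#'   rows), `annotations` (sample annotation tibble), `truth` (the
#'   planted-effect tibble), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config
  n <- sum(cfg$histology_sizes)

  effect_mirnas <- unique(cfg$effects$mirna_id)
  n_fill <- cfg$n_mirnas - length(effect_mirnas)
  mirna_ids <- c(effect_mirnas,
                 sprintf("miR-sim-%03d", seq_len(max(n_fill, 0L))))
  spike_ids <- sprintf("SPIKE_%02d", seq_len(cfg$n_spikeins))
  sample_ids <- sprintf("EC%03d", seq_len(n))

  withr::with_seed(derive_seed(cfg$seed, "cohort"), {
    ann <- simulate_annotations(cfg, sample_ids)

    # baseline log2 expression relative to the spike-in reference
    b <- stats::rnorm(cfg$n_mirnas,
                      mean = cfg$spikein_ct - cfg$baseline_ct_mean,
                      sd = cfg$baseline_ct_sd)
    expr <- matrix(b, nrow = cfg$n_mirnas, ncol = n)
    dimnames(expr) <- list(mirna_ids, sample_ids)
    for (i in seq_len(nrow(cfg$effects))) {
      e <- cfg$effects[i, ]
      in_group <- ann[[e$variable]] == e$level
      expr[e$mirna_id, in_group] <- expr[e$mirna_id, in_group] + log2(e$fold_change)
    }
    expr <- expr + matrix(stats::rnorm(length(expr), sd = cfg$noise_sd),
                          nrow = nrow(expr))

    shift <- stats::rnorm(n, sd = cfg$sample_shift_sd)
    ct <- sweep(cfg$spikein_ct - expr, 2L, shift, FUN = "+")
    ct[ct > cfg$detection_limit] <- NA_real_
    ct <- pmax(ct, 0)

    spike_base <- stats::rnorm(cfg$n_spikeins, mean = cfg$spikein_ct, sd = 0.5)
    spike_ct <- outer(spike_base, shift, FUN = "+")
    dimnames(spike_ct) <- list(spike_ids, sample_ids)
  })

  full <- rbind(ct, spike_ct)
  ct_tbl <- ct_matrix(matrix_to_wide(full, "assay_id"), spike_in_ids = spike_ids)
  structure(list(ct = ct_tbl, annotations = ann,
                 truth = cfg$effects, config = cfg),
            class = "mirna_cohort")
}

# Draw per-sample subtype labels under the configured group structure.
# Molecular labels are independent of histology; CTNNB1-mutated samples
# are preferentially endometrioid (about 17 of 19 at the defaults).
simulate_annotations <- function(cfg, sample_ids) {
  n <- length(sample_ids)
  histology <- rep(names(cfg$histology_sizes), cfg$histology_sizes)

  grade <- rep(NA_character_, n)
  endo <- which(histology == "endometrioid")
  if (length(endo)) {
    # grade mix for endometrioid tumors: roughly 33/33/23 across G1/G2/G3
    g <- rep(GRADE_LEVELS, times = round(length(endo) * c(33, 33, 23) / 89))
    grade[endo] <- rep_len(c(g, GRADE_LEVELS), length(endo))[seq_along(endo)]
  }

  molecular <- rep("unknown", n)
  n_subtyped <- sum(cfg$molecular_sizes)
  if (n_subtyped > 0) {
    subtyped <- sample(n, n_subtyped)
    molecular[subtyped] <- sample(rep(names(cfg$molecular_sizes), cfg$molecular_sizes))
  }

  ctnnb1 <- rep("unknown", n)
  if (cfg$n_sequenced > 0) {
    k_endo <- min(round(cfg$ctnnb1_n_mutated * 17 / 19), length(endo))
    k_other <- cfg$ctnnb1_n_mutated - k_endo
    others <- setdiff(seq_len(n), endo)
    mutated <- c(sample(endo, k_endo), sample(others, min(k_other, length(others))))
    sequenced <- union(mutated, sample(n, cfg$n_sequenced))[seq_len(cfg$n_sequenced)]
    ctnnb1[sequenced] <- "wildtype"
    ctnnb1[mutated] <- "mutated"
  }

  validate_annotations(tibble::tibble(
    sample_id = sample_ids, histology = histology, grade = grade,
    molecular = molecular, ctnnb1 = ctnnb1))
}

#' @export
print.mirna_cohort <- function(x, ...) {
  cat(sprintf("<mirna_cohort> %d assays (%d spike-ins) x %d samples, %d planted effects, seed %d\n",
              nrow(x$ct), length(spike_in_ids(x$ct)), ncol(x$ct) - 1L,
              nrow(x$truth), x$config$seed))
  invisible(x)
}

#' Join planted truth to screen output
#'
#' Reports, per planted effect of one contrast, whether the downstream
#' screen detected it (permutation p below the screen's alpha) and the
#' estimated fold change, for power and bias checks against ground truth.
#'
#' @param truth Planted-effect tibble (columns `mirna_id`, `fold_change`,
#'   optionally `variable`/`level`).
#' @param screen A [run_screen()] result on a cohort generated with
#'   `truth`.
#' @return Tibble with `mirna_id`, `true_fc`, `estimated_fc`, `perm_p`,
#'   `detected`.
#' @export
effect_recovery_report <- function(truth, screen) {
  truth <- tibble::as_tibble(truth)
  alpha <- attr(screen, "alpha") %||% 0.05
  if (!nrow(truth)) {
    return(tibble::tibble(mirna_id = character(), true_fc = double(),
                          estimated_fc = double(), perm_p = double(),
                          detected = logical()))
  }
  dplyr::left_join(
    dplyr::select(truth, "mirna_id", true_fc = "fold_change"),
    dplyr::select(tibble::as_tibble(screen), "mirna_id",
                  estimated_fc = "fold_change", "perm_p"),
    by = "mirna_id"
  ) |>
    dplyr::mutate(detected = !is.na(.data$perm_p) & .data$perm_p < alpha)
}
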