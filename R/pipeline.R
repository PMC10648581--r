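# Orchestration: simulation/ingest -> normalization -> screens -> models,
# with every artifact checksummed into a run manifest.

#' Configure a pipeline run
#'
#' Exactly one input source must be given: either `simulate` (a
#' [cohort_config()]) or both `ct_path` and `ann_path` pointing at TSV
#' files. The global `seed` fans out to per-stage seeds by stable hashing
#' of stage names, so every stage is individually reproducible; it also
#' overrides the seeds carried inside `simulate` and `sfs`.
#'
#' @param simulate Optional [cohort_config()] for a synthetic run.
#' @param ct_path,ann_path Optional paths to a Ct matrix TSV and a sample
#'   annotation TSV.
#' @param spike_in_prefix Prefix flagging spike-in rows when reading
#'   `ct_path`.
#' @param detection_limit,max_missing_frac Passed to [normalize_ct()].
#' @param alpha,n_permutations,fc_threshold Screen parameters (defaults
#'   0.05, 1000, 0.5).
#' @param screen_targets Tibble of `(variable, level)` contrasts to
#'   screen; defaults to every histological and molecular subtype plus
#'   CTNNB1-mutated.
#' @param model_targets Tibble of `(variable, level)` targets passed to
#'   [build_subtype_models()].
#' @param sfs An [sfs_config()].
#' @param outdir Output directory (created if needed).
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = NULL, ct_path = NULL, ann_path = NULL,
                       spike_in_prefix = "SPIKE_",
                       detection_limit = 38, max_missing_frac = 0.2,
                       alpha = 0.05, n_permutations = 1000, fc_threshold = 0.5,
                       screen_targets = default_screen_targets(),
                       model_targets = default_model_targets(),
                       sfs = sfs_config(),
                       outdir = tempfile("mirsubtype_run_"),
                       seed = 1L) {
  has_paths <- !is.null(ct_path) || !is.null(ann_path)
  if (is.null(simulate) && !(length(ct_path) && length(ann_path))) {
    abort("Provide either `simulate` or both `ct_path` and `ann_path`.",
          class = "mirsubtype_config_error")
  }
  if (!is.null(simulate) && has_paths) {
    abort("`simulate` and input paths are mutually exclusive.",
          class = "mirsubtype_config_error")
  }
  structure(list(simulate = simulate, ct_path = ct_path, ann_path = ann_path,
                 spike_in_prefix = spike_in_prefix,
                 detection_limit = detection_limit,
                 max_missing_frac = max_missing_frac,
                 alpha = alpha, n_permutations = n_permutations,
                 fc_threshold = fc_threshold,
                 screen_targets = tibble::as_tibble(screen_targets),
                 model_targets = tibble::as_tibble(model_targets),
                 sfs = sfs, outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_screen_targets <- function() {
  dplyr::bind_rows(
    tibble::tibble(variable = "histology", level = HISTOLOGY_LEVELS),
    tibble::tibble(variable = "molecular", level = MOLECULAR_LEVELS),
    tibble::tibble(variable = "ctnnb1", level = "mutated"))
}

#' Run the full pipeline
#'
#' Executes simulation (or ingest), spike-in normalization, one
#' differential screen per configured contrast, and sequential forward
#' selection per model target, writing every artifact under
#' `config$outdir`: input TSVs, the normalized expression TSV, one screen
#' TSV + JSON parameter sidecar + rendered top table per contrast, a
#' direction-count summary, one model JSON + ROC-points TSV per target,
#' and a manifest listing every artifact with its MD5 checksum. Rerunning
#' with the same config reproduces identical checksums.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest tibble (`file`, `md5`), invisibly; also written
#'   to `manifest.tsv`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  artifacts <- character()
  emit <- function(path) artifacts <<- c(artifacts, path)

  # --- inputs -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- derive_seed(config$seed, "simulate")
    say("simulate: %d assays x %d samples (seed %d)",
        sim_cfg$n_mirnas + sim_cfg$n_spikeins,
        sum(sim_cfg$histology_sizes), sim_cfg$seed)
    cohort <- generate_cohort(sim_cfg)
    ct <- cohort$ct
    ann <- cohort$annotations
    emit(write_ct_matrix(ct, file.path(out, "ct_matrix.tsv")))
    emit(write_annotations(ann, file.path(out, "annotations.tsv")))
    emit(write_tsv_artifact(cohort$truth, file.path(out, "planted_effects.tsv")))
  } else {
    say("ingest: %s + %s", config$ct_path, config$ann_path)
    ct <- read_ct_matrix(config$ct_path, config$spike_in_prefix)
    ann <- read_annotations(config$ann_path)
  }

  # --- normalization ------------------------------------------------
  say("normalize: spike-in median reference, detection limit %g",
      config$detection_limit)
  expr <- normalize_ct(ct, config$detection_limit, config$max_missing_frac)
  emit(write_expression_matrix(expr, file.path(out, "expression.tsv")))

  # --- screens ------------------------------------------------------
  summaries <- list()
  for (i in seq_len(nrow(config$screen_targets))) {
    variable <- config$screen_targets$variable[i]
    level <- config$screen_targets$level[i]
    tag <- paste0(variable, "_", level)
    scr <- tryCatch({
      contrast <- make_contrast(ann, variable, level, samples = names(expr)[-1L])
      run_screen(expr, contrast, alpha = config$alpha,
                 B = config$n_permutations,
                 fc_threshold = config$fc_threshold,
                 seed = derive_seed(config$seed, "screen", tag))
    }, mirsubtype_contrast_error = function(e) {
      warn(sprintf("Skipping screen %s: %s", tag, conditionMessage(e)))
      NULL
    })
    if (is.null(scr)) next
    g <- glance(scr)
    say("screen %s: %d significant, %d pass FC filter", tag,
        g$n_significant, g$n_pass_fc_filter)
    emit(write_tsv_artifact(tidy(scr), file.path(out, paste0("screen_", tag, ".tsv"))))
    emit(write_json_artifact(as.list(g), file.path(out, paste0("screen_", tag, ".json"))))
    emit(write_tsv_artifact(render_top_table(scr),
                            file.path(out, paste0("top_table_", tag, ".tsv"))))
    summaries[[tag]] <- g
  }
  if (length(summaries)) {
    emit(write_tsv_artifact(dplyr::bind_rows(summaries),
                            file.path(out, "screen_summary.tsv")))
  }

  # --- models -------------------------------------------------------
  sfs <- config$sfs
  sfs$seed <- derive_seed(config$seed, "select")
  models <- build_subtype_models(expr, ann, targets = config$model_targets,
                                 config = sfs)
  for (name in names(models)) {
    model <- models[[name]]
    tag <- gsub(":", "_", name, fixed = TRUE)
    say("model %s: %d miRNAs, mean CV AUC %.3f", name,
        length(model$selected_mirnas), model$mean_auc)
    emit(write_json_artifact(model_as_list(model),
                             file.path(out, paste0("model_", tag, ".json"))))
    emit(write_tsv_artifact(roc_points(model),
                            file.path(out, paste0("roc_", tag, ".tsv"))))
  }

  manifest <- tibble::tibble(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts))) |>
    dplyr::arrange(.data$file)
  readr::write_tsv(manifest, file.path(out, "manifest.tsv"))
  say("done: %d artifacts under %s", nrow(manifest), out)
  invisible(manifest)
}

write_tsv_artifact <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "NA")
  path
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

model_as_list <- function(model) {
  list(contrast_name = model$contrast_name,
       selected_mirnas = as.list(model$selected_mirnas),
       mean_auc = model$mean_auc,
       repeat_aucs = model$repeat_aucs,
       selection_trace = model$selection_trace,
       weights = as.list(model$scorer$weights),
       intercept = model$scorer$intercept,
       n_positive = model$n_positive,
       n_negative = model$n_negative,
       n_folds = model$config$n_folds,
       n_repeats = model$config$n_repeats,
       regularization = model$config$regularization,
       seed = model$config$seed)
}

#' Render a publication-style top table
#'
#' Fold-change-filter survivors of a screen (restricted to significant
#' records when a `significant` column is present), grouped into an
#' increased and a decreased block and sorted within each block by
#' |log2 fold change| descending; fold changes are rounded to 2 decimals
#' for display.
#'
#' @param screen A [run_screen()] result (or any tibble with
#'   `fold_change`).
#' @param fc_threshold Filter threshold; defaults to the screen's own.
#' @return Tibble with `direction`, `mirna_id`, `fold_change` (2 dp) and,
#'   when available, `perm_p`.
#' @export
render_top_table <- function(screen, fc_threshold = NULL) {
  fc_threshold <- fc_threshold %||% attr(screen, "fc_threshold") %||% 0.5
  rec <- tibble::as_tibble(screen)
  if ("significant" %in% names(rec)) rec <- rec[rec$significant, , drop = FALSE]
  rec <- fc_filter(rec, fc_threshold)
  if (!"mirna_id" %in% names(rec)) rec$mirna_id <- NA_character_
  rec$direction <- ifelse(rec$fold_change > 1, "increased", "decreased")
  rec <- rec[order(rec$direction == "decreased",
                   -abs(log2(rec$fold_change))), , drop = FALSE]
  out <- tibble::tibble(direction = rec$direction,
                        mirna_id = rec$mirna_id,
                        fold_change = round(rec$fold_change, 2))
  if ("perm_p" %in% names(rec)) out$perm_p <- rec$perm_p
  out
}
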