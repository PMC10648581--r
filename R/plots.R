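# ggplot2 displays for screen results and fitted subtype models.

#' Volcano plot of a differential screen
#'
#' log2 fold change against -log10 permutation p, with the significance
#' threshold and the fold-change filter bounds drawn as reference lines.
#'
#' @param object A `mirna_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirna_screen <- function(object, ...) {
  df <- tidy(object)
  alpha <- attr(object, "alpha")
  thr <- attr(object, "fc_threshold")
  df$status <- dplyr::case_when(
    df$significant & df$passes_fc_filter ~ "significant + FC filter",
    df$significant ~ "significant",
    .default = "not significant")
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fold_change),
                                   y = -log10(.data$perm_p),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = log2(c(1 - thr, 1 + thr)),
                        linetype = "dotted") +
    ggplot2::labs(title = attr(object, "contrast_name"),
                  x = "log2 fold change (group vs rest)",
                  y = "-log10 permutation p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Direction counts across screens
#'
#' Bar chart of the number of significantly increased and decreased
#' miRNAs per contrast, from one or more screen results.
#'
#' @param screens A single `mirna_screen` or a list of them.
#' @return A ggplot object.
#' @export
plot_direction_counts <- function(screens) {
  if (inherits(screens, "mirna_screen")) screens <- list(screens)
  df <- purrr::map_dfr(screens, glance) |>
    tidyr::pivot_longer(c("n_increased", "n_decreased"),
                        names_to = "direction", values_to = "n") |>
    dplyr::mutate(direction = ifelse(.data$direction == "n_increased",
                                     "increased", "decreased"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contrast, y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "significant miRNAs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' ROC curve of a fitted subtype model
#'
#' Pooled held-out scores from the evaluation repeat, with the mean
#' cross-validated AUC in the subtitle.
#'
#' @param object A `subtype_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subtype_model <- function(object, ...) {
  pts <- roc_points(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$contrast_name,
                  subtitle = sprintf("%d-miRNA panel, mean CV AUC %.2f",
                                     length(object$selected_mirnas),
                                     object$mean_auc),
                  x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
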