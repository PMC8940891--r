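#' Plot a PCoA ordination
#'
#' Scatter of the first two principal coordinates with eigenvalue shares in
#' the axis labels.
#'
#' @param object A `pcoa_ord` from [pcoa_ordination()].
#' @param colour Optional vector (aligned to samples) to colour points by,
#'   e.g. the group column of the metadata.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_ord <- function(object, colour = NULL, ...) {
  df <- object$scores
  ve <- 100 * object$variance_explained
  p <- if (is.null(colour)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2))
  } else {
    df$colour <- colour
    ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2,
                                     colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", ve[1]),
                  y = sprintf("PCo2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation error curve
#'
#' Mean misclassification error against marker count with a +/- 1 SE
#' ribbon; the dashed line marks the minimum-plus-SE cutoff used by
#' [select_markers()].
#'
#' @param object An `error_curve` from [cv_error_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_curve <- function(object, ...) {
  i_min <- which.min(object$mean_error)
  cutoff <- object$mean_error[i_min] + object$se[i_min]
  ggplot2::ggplot(object, ggplot2::aes(.data$marker_count,
                                       .data$mean_error)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_error - .data$se,
                                      ymax = .data$mean_error + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "number of markers", y = "CV error") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential features
#'
#' @param object A `diff_features` tibble.
#' @param ... Unused.
#' @return A ggplot object (log2 fold change vs -log10 q, coloured by the
#'   univariate pass flag).
#' @export
autoplot.diff_features <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(log2(.data$fold_change),
                                   -log10(.data$q_value),
                                   colour = .data$passes_univariate)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "log2 fold change (case/control)", y = "-log10 q",
                  colour = "FDR pass") +
    ggplot2::theme_minimal()
}

#' Heatmap of species-metabolite associations
#'
#' Tile heatmap of discovery Spearman correlations; discovered pairs
#' (q below the cutoff) are outlined.
#'
#' @param object An `assoc_matrix` from [association_heatmap_data()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assoc_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame.table(object$r,
                                              responseName = "r"),
                          .name_repair = "minimal")
  names(df)[1:2] <- c("species_id", "metabolite_id")
  df$discovered <- as.vector(object$mask)
  ggplot2::ggplot(df, ggplot2::aes(.data$metabolite_id, .data$species_id,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$discovered, ], fill = NA,
                       colour = "black", linewidth = 0.3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' ROC curve for a marker model
#'
#' @param model A `marker_model` with per-sample scores.
#' @return A ggplot object of the ROC curve with the AUC in the subtitle.
#' @export
plot_roc <- function(model) {
  stopifnot(inherits(model, "marker_model"))
  s <- model$scores
  thr <- sort(unique(c(-Inf, s$score, Inf)), decreasing = TRUE)
  pts <- purrr::map_dfr(thr, function(t) {
    tibble::tibble(fpr = mean(s$score[s$label == 0] >= t),
                   tpr = mean(s$score[s$label == 1] >= t))
  })
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("%s AUC = %.3f (95%% CI %.3f-%.3f)",
                                     model$cohort, model$auc,
                                     model$auc_ci[1], model$auc_ci[2])) +
    ggplot2::theme_minimal()
}
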