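#' Tidy a marker model
#'
#' One row per selected marker with its forest importance and rank.
#'
#' @param x A `marker_model`.
#' @param ... Unused.
#' @return A tibble: `feature_id`, `importance`, `rank`.
#' @export
tidy.marker_model <- function(x, ...) {
  x$ranking |>
    dplyr::filter(.data$feature_id %in% x$selected_features)
}

#' Glance at a marker model
#'
#' @param x A `marker_model`.
#' @param ... Unused.
#' @return One-row tibble: `cohort`, `n_selected`, `auc`, `ci_lo`, `ci_hi`.
#' @export
glance.marker_model <- function(x, ...) {
  tibble::tibble(cohort = x$cohort, n_selected = x$n_selected,
                 auc = x$auc, ci_lo = x$auc_ci[1], ci_hi = x$auc_ci[2])
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf("<marker_model> %s cohort: %d markers, AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$cohort, x$n_selected, x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' Tidy a PCoA ordination
#'
#' @param x A `pcoa_ord`.
#' @param ... Unused.
#' @return The per-sample scores tibble.
#' @export
tidy.pcoa_ord <- function(x, ...) x$scores

#' Glance at a PCoA ordination
#'
#' @param x A `pcoa_ord`.
#' @param ... Unused.
#' @return One-row tibble with the variance share per returned axis.
#' @export
glance.pcoa_ord <- function(x, ...) {
  v <- x$variance_explained
  tibble::as_tibble(setNames(as.list(v), paste0("axis", seq_along(v),
                                                "_share")))
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d cases / %d controls; %d species, %d metabolites/table\n",
              x$n_case, x$n_control, x$n_species, x$n_metabolites))
  cat(sprintf("  planted: %.0f%% differential (log-effect %.3f), clusters [%s] at r=%.2f, %d couplings at |r|=%.2f\n",
              100 * x$frac_differential, x$log_fold_effect,
              paste(x$cluster_sizes, collapse = ","), x$cluster_corr,
              x$n_associations, x$assoc_strength))
  invisible(x)
}

#' @export
print.momics_cohort <- function(x, ...) {
  cat(sprintf("<momics_cohort> %d samples; %d species, %d fecal + %d serum metabolites (seed %d)\n",
              nrow(x$metadata), ncol(x$microbiome) - 1,
              ncol(x$fecal_mets) - 1, ncol(x$serum_mets) - 1,
              x$truth$seed))
  invisible(x)
}
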