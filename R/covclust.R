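#' Additively smooth zeros by half the per-sample minimum
#'
#' Within each sample, zero intensities are replaced by half the smallest
#' non-zero measurement of that sample; non-zero values are untouched.
#'
#' @param data Feature tibble; every sample must have at least one non-zero
#'   value.
#' @return The smoothed feature tibble.
#' @export
smooth_zeros <- function(data) {
  m <- ft_matrix(data)
  check_nonnegative(m)
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    nz <- row[row > 0]
    if (length(nz) == 0) {
      stop(sprintf("sample '%s' is all zero; cannot smooth", rownames(m)[i]),
           call. = FALSE)
    }
    row[row == 0] <- min(nz) / 2
    m[i, ] <- row
  }
  ft_tibble(m)
}

#' Elementwise natural-log transform
#'
#' Variance-stabilizing log transform; values must be strictly positive, so
#' run [smooth_zeros()] first on tables containing zeros.
#'
#' @param data Feature tibble with strictly positive values.
#' @return The log-scale feature tibble.
#' @export
log_transform <- function(data) {
  m <- ft_matrix(data)
  if (any(m <= 0)) {
    idx <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive value at sample '%s', feature '%s'; apply smooth_zeros() first",
                 rownames(m)[idx[1]], colnames(m)[idx[2]]), call. = FALSE)
  }
  ft_tibble(log(m))
}

#' Residualize log abundances against phenotype and age
#'
#' Models each feature's (log-scale) abundance by ordinary least squares on
#' an intercept, a dummy-coded phenotype and a continuous age covariate, and
#' returns the residuals. Residuals are what the covariation clustering
#' operates on, so that clusters reflect shared variation beyond the
#' phenotype/age structure.
#'
#' @param data Log-scale feature tibble.
#' @param metadata Metadata tibble with `sample_id` and the covariates.
#' @param phenotype Name of a categorical metadata column with >= 2 levels.
#' @param age Name of a continuous metadata column (`NULL` to omit).
#' @return A residual tibble (same shape as `data`; values may be
#'   negative), with the model description in the `"model"` attribute.
#' @export
residualize <- function(data, metadata, phenotype = "group", age = "age") {
  m <- ft_matrix(data)
  md <- metadata[match(rownames(m), metadata$sample_id), ]
  ph <- droplevels(as.factor(md[[phenotype]]))
  if (nlevels(ph) < 2) stop("phenotype must have at least 2 levels")
  X <- if (is.null(age)) model.matrix(~ph)
       else model.matrix(~ ph + a, data.frame(ph = ph, a = as.numeric(md[[age]])))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
                       collapse = ", ")), call. = FALSE)
  }
  fit <- lm.fit(X, m)
  res <- fit$residuals
  dimnames(res) <- dimnames(m)
  out <- ft_tibble(res)
  attr(out, "model") <- sprintf("~ %s%s", phenotype,
                                if (is.null(age)) "" else paste0(" + ", age))
  out
}

#' Greedy covariation clustering of residual abundances
#'
#' Single sequential pass over features in `ranking` order (highest fold
#' change first by convention): the first feature seeds cluster 1; each
#' subsequent feature joins the first extant cluster (in creation order)
#' whose members' mean Spearman correlation with it strictly exceeds
#' `r_threshold`, else seeds a new cluster. Afterwards clusters are
#' renumbered by size, largest first (ties: earlier seed first).
#'
#' @param residuals Residual feature tibble (see [residualize()]).
#' @param ranking Character vector: a permutation of the feature ids giving
#'   the scan order. Defaults to column order.
#' @param r_threshold Similarity threshold in (-1, 1); default 0.7.
#' @param similarity `"signed"` (default; strong negative correlations
#'   repel) or `"absolute"`.
#' @param assign `"first"` (default; join the first eligible cluster) or
#'   `"best"` (join the eligible cluster with the highest mean similarity).
#' @return A tibble of class `cluster_assignment`: `feature_id`, `cluster`
#'   (1-based, sizes non-increasing), `is_seed`.
#' @export
greedy_cluster <- function(residuals, ranking = NULL, r_threshold = 0.7,
                           similarity = c("signed", "absolute"),
                           assign = c("first", "best")) {
  similarity <- match.arg(similarity)
  assign <- match.arg(assign)
  if (r_threshold <= -1 || r_threshold >= 1) {
    stop("r_threshold must lie in (-1, 1)", call. = FALSE)
  }
  m <- ft_matrix(residuals)
  feats <- colnames(m)
  if (is.null(ranking)) ranking <- feats
  if (!setequal(ranking, feats) || length(ranking) != length(feats)) {
    stop("ranking must be a permutation of the residual feature ids",
         call. = FALSE)
  }
  rmat <- suppressWarnings(cor(m, method = "spearman"))
  if (similarity == "absolute") rmat <- abs(rmat)
  clusters <- list()   # in creation order; each a character vector
  seeds <- character()
  for (f in ranking) {
    sims <- vapply(clusters, function(members) mean(rmat[f, members]),
                   numeric(1))
    eligible <- which(sims > r_threshold)
    if (length(eligible) == 0) {
      clusters[[length(clusters) + 1]] <- f
      seeds <- c(seeds, f)
    } else {
      pick <- if (assign == "first") eligible[1]
              else eligible[which.max(sims[eligible])]
      clusters[[pick]] <- c(clusters[[pick]], f)
    }
  }
  # renumber by size descending; ties keep creation (seed) order
  ord <- order(-lengths(clusters), seq_along(clusters))
  out <- dplyr::bind_rows(purrr::imap(clusters[ord], function(members, i) {
    tibble::tibble(feature_id = members, cluster = i,
                   is_seed = members == members[1])
  }))
  class(out) <- c("cluster_assignment", class(out))
  attr(out, "r_threshold") <- r_threshold
  out
}

#' Per-cluster enrichment summary
#'
#' Joins a cluster assignment with differential-feature directions and
#' summarizes each cluster: size, counts by enrichment direction, the
#' majority direction and its unanimity.
#'
#' @param assignment A `cluster_assignment` from [greedy_cluster()].
#' @param differentials A `diff_features` tibble covering all clustered
#'   features.
#' @return Tibble: `cluster`, `size`, `n_case_enriched`,
#'   `n_control_enriched`, `majority_direction`, `unanimity`.
#' @export
cluster_summary <- function(assignment, differentials) {
  if (nrow(assignment) == 0) {
    return(tibble::tibble(cluster = integer(), size = integer(),
                          n_case_enriched = integer(),
                          n_control_enriched = integer(),
                          majority_direction = character(),
                          unanimity = numeric()))
  }
  missing <- setdiff(assignment$feature_id, differentials$feature_id)
  if (length(missing) > 0) {
    stop(sprintf("clustered feature '%s' not present in differentials",
                 missing[1]), call. = FALSE)
  }
  assignment |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(differentials), "feature_id",
                    "direction"),
      by = "feature_id") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      size = dplyr::n(),
      n_case_enriched = sum(.data$direction == "case_enriched"),
      n_control_enriched = sum(.data$direction == "control_enriched"),
      majority_direction = ifelse(n_case_enriched >= n_control_enriched,
                                  "case_enriched", "control_enriched"),
      unanimity = pmax(n_case_enriched, n_control_enriched) / dplyr::n(),
      .groups = "drop") |>
    dplyr::arrange(.data$cluster)
}
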