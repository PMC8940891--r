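#' Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon (Mann-Whitney) test. Uses exact enumeration when both
#' groups have at most 8 observations and no ties occur, otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param a,b Numeric vectors with at least 3 observations each.
#' @return List with `statistic` (the Mann-Whitney U for `a`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values with enforced monotonicity, clipped at 1, in the
#' input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Fold change between group means
#'
#' Ratio of case mean to control mean on the raw (unlogged) scale. Run on
#' zero-smoothed intensities (see [smooth_zeros()]) so the control mean is
#' positive.
#'
#' @param case,control Numeric vectors.
#' @return A single ratio; `NA` with a warning when the control mean is 0.
#' @export
fold_change <- function(case, control) {
  mc <- mean(case, na.rm = TRUE)
  m0 <- mean(control, na.rm = TRUE)
  if (!is.finite(m0) || m0 <= 0) {
    warning("control mean is zero; fold change undefined")
    return(NA_real_)
  }
  mc / m0
}

#' PLS-DA variable importance in projection (VIP) scores
#'
#' Fits a partial least squares discriminant model (NIPALS, single
#' dummy-coded response) on column-standardized `X` and returns per-feature
#' VIP scores:
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )`,
#' where `p` is the feature count, `w_a` the unit-norm weight vector of
#' component `a` and `SSY_a` the response variance explained by that
#' component. The mean of squared VIPs is exactly 1.
#'
#' @param X Numeric samples-by-features matrix.
#' @param y Binary labels (two distinct values).
#' @param n_components Number of PLS components (default 2, truncated to
#'   the available rank).
#' @return Named numeric vector of VIP scores (one per column of `X`).
#' @export
plsda_vip <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  if (length(unique(y)) != 2) stop("y must have exactly two classes")
  yy <- as.numeric(as.factor(y)) - 1
  p <- ncol(X)
  n <- nrow(X)
  stopifnot(length(yy) == n, n_components >= 1)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  constant <- sdev < .Machine$double.eps
  sdev[constant] <- 1  # constant features get zero weight via zero covariance
  E <- sweep(sweep(X, 2, mu), 2, sdev, `/`)
  E[, constant] <- 0
  f <- yy - mean(yy)
  A <- min(n_components, n - 1, p)
  W <- matrix(0, p, A)
  ssy <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1; break }
    w <- w / nw
    t_sc <- drop(E %*% w)
    tt <- sum(t_sc^2)
    if (tt < 1e-12) { A <- a - 1; break }
    p_load <- drop(crossprod(E, t_sc)) / tt
    q_load <- sum(f * t_sc) / tt
    ssy[a] <- q_load^2 * tt
    W[, a] <- w
    E <- E - tcrossprod(t_sc, p_load)
    f <- f - q_load * t_sc
  }
  if (A < 1) stop("no usable PLS component (response orthogonal to X)")
  W <- W[, seq_len(A), drop = FALSE]
  ssy <- ssy[seq_len(A)]
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(X)
  vip
}

#' Differential-feature selection criteria
#'
#' Two modes reflect the two published conventions: `"univariate"` flags
#' features at BH FDR below `q_cutoff` (default 0.05); `"combined"` further
#' requires PLS-DA VIP above `vip_cutoff` (default 1.0) and a fold change
#' outside the near-null band `fc_band` (default 0.8-1.2; set
#' `fc_band_mode = "include"` for the literal inside-the-band reading), with
#' `q_cutoff` defaulting to 0.1.
#'
#' @param mode `"univariate"` or `"combined"`.
#' @param q_cutoff FDR cutoff; defaults to 0.05 (univariate) or 0.1
#'   (combined).
#' @param vip_cutoff VIP threshold (strict `>`).
#' @param fc_band Two-element fold-change band around 1.
#' @param fc_band_mode `"exclude"` (differential features lie outside the
#'   band) or `"include"`.
#' @param n_components PLS components for the VIP fit.
#' @return A `criteria_config` list.
#' @export
criteria_config <- function(mode = c("univariate", "combined"),
                            q_cutoff = NULL, vip_cutoff = 1.0,
                            fc_band = c(0.8, 1.2),
                            fc_band_mode = c("exclude", "include"),
                            n_components = 2) {
  mode <- match.arg(mode)
  fc_band_mode <- match.arg(fc_band_mode)
  if (is.null(q_cutoff)) q_cutoff <- if (mode == "univariate") 0.05 else 0.1
  stopifnot(q_cutoff > 0, q_cutoff < 1,
            length(fc_band) == 2, fc_band[1] < 1, fc_band[2] > 1,
            n_components >= 1)
  structure(list(mode = mode, q_cutoff = q_cutoff, vip_cutoff = vip_cutoff,
                 fc_band = fc_band, fc_band_mode = fc_band_mode,
                 n_components = n_components),
            class = "criteria_config")
}

#' Identify differentially abundant features
#'
#' Per feature: two-sided Wilcoxon rank-sum p between cases and controls,
#' BH q across all features of the table, fold change (case mean / control
#' mean on zero-smoothed raw values), and in combined mode a PLS-DA VIP
#' score fit on log-transformed zero-smoothed values. Pass flags follow the
#' [criteria_config()] mode.
#'
#' @param data Feature tibble.
#' @param metadata Metadata tibble with `sample_id` and a group column.
#' @param criteria A [criteria_config()].
#' @param group_col,case,control Group column name and its case/control
#'   labels.
#' @return A tibble of class `diff_features`, one row per feature
#'   (`feature_id`, `p_value`, `q_value`, `fold_change`, `vip`,
#'   `direction`, `passes_univariate`, `passes_combined`), ordered by
#'   ascending q then feature id.
#' @export
differential_features <- function(data, metadata,
                                  criteria = criteria_config(),
                                  group_col = "group", case = "IBS",
                                  control = "HC") {
  m <- ft_matrix(data)
  check_nonnegative(m)
  md <- metadata[match(rownames(m), metadata$sample_id), ]
  g <- md[[group_col]]
  idx_case <- which(g == case)
  idx_ctrl <- which(g == control)
  if (length(idx_case) < 3 || length(idx_ctrl) < 3) {
    stop("need at least 3 samples per group", call. = FALSE)
  }
  sm <- ft_matrix(smooth_zeros(data))

  p_values <- vapply(seq_len(ncol(m)), function(j) {
    wilcoxon_rank_sum(m[idx_case, j], m[idx_ctrl, j])$p_value
  }, numeric(1))
  q_values <- bh_fdr(p_values)
  fc <- vapply(seq_len(ncol(sm)), function(j) {
    fold_change(sm[idx_case, j], sm[idx_ctrl, j])
  }, numeric(1))

  vip <- rep(NA_real_, ncol(m))
  if (criteria$mode == "combined") {
    keep <- c(idx_case, idx_ctrl)
    vip <- unname(plsda_vip(log(sm[keep, , drop = FALSE]),
                            g[keep] == case,
                            n_components = criteria$n_components))
  }

  outside_band <- fc <= criteria$fc_band[1] | fc >= criteria$fc_band[2]
  fc_ok <- if (criteria$fc_band_mode == "exclude") outside_band else !outside_band
  res <- tibble::tibble(
    feature_id = colnames(m),
    p_value = p_values,
    q_value = q_values,
    fold_change = fc,
    vip = vip,
    direction = ifelse(fc >= 1, "case_enriched", "control_enriched"),
    passes_univariate = q_values < criteria$q_cutoff,
    passes_combined = if (criteria$mode == "combined") {
      q_values < criteria$q_cutoff & vip > criteria$vip_cutoff & fc_ok
    } else NA
  ) |>
    dplyr::arrange(.data$q_value, .data$feature_id)
  class(res) <- c("diff_features", class(res))
  attr(res, "criteria") <- criteria
  res
}
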