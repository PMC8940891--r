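# Random-forest marker selection. The forest itself (CART trees, Gini
# splits, bootstrap resampling, mtry = sqrt(p), mean-decrease-in-impurity
# importance, vote-fraction probabilities) is implemented in C++ (see
# src/forest.cpp) with its own deterministic RNG, so results depend only on
# the seed arguments, not on R's RNG state.

rf_mtry <- function(p) max(1L, floor(sqrt(p)))

encode_labels <- function(y) {
  f <- as.factor(y)
  if (nlevels(f) != 2) stop("y must have exactly two classes", call. = FALSE)
  list(y01 = as.integer(f) - 1L, levels = levels(f))
}

#' Rank features by random-forest importance
#'
#' Fits a forest on the full data (500 trees, `sqrt(p)` candidate features
#' per split) and orders features by mean decrease in Gini impurity.
#' Deterministic for a given seed.
#'
#' @param data Feature tibble.
#' @param y Binary labels aligned to the rows of `data`.
#' @param ntree Number of trees (default 500).
#' @param seed Integer seed.
#' @return Tibble: `feature_id`, `importance`, `rank` (1 = most important;
#'   ties broken by column order).
#' @export
rank_features <- function(data, y, ntree = 500, seed = 1L) {
  m <- ft_matrix(data)
  if (nrow(m) < 10) stop("need at least 10 samples", call. = FALSE)
  enc <- encode_labels(y)
  imp <- rf_importance_cpp(m, enc$y01, as.integer(ntree),
                           rf_mtry(ncol(m)), 1L, as.integer(seed))
  ord <- order(-imp, seq_along(imp))
  tibble::tibble(feature_id = colnames(m)[ord],
                 importance = imp[ord],
                 rank = seq_along(ord))
}

stratified_folds <- function(y01, n_folds, seed) {
  idx1 <- which(y01 == 1); idx0 <- which(y01 == 0)
  if (min(length(idx0), length(idx1)) < n_folds) {
    # every fold must be able to hold both classes in training; with fewer
    # minority samples than folds some folds would lack a class entirely
    if (min(length(idx0), length(idx1)) < 2) {
      stop("cannot build stratified folds: a class has fewer than 2 samples",
           call. = FALSE)
    }
  }
  set.seed(seed)
  fold <- integer(length(y01))
  fold[idx1] <- sample(rep_len(seq_len(n_folds), length(idx1)))
  fold[idx0] <- sample(rep_len(seq_len(n_folds), length(idx0)))
  fold
}

#' Cross-validation error curve over nested marker counts
#'
#' For each marker count `c` in `counts`, trains a forest on the top-`c`
#' features of `ranked_features` within each training fold and records the
#' test-fold misclassification rate (vote-fraction probability thresholded
#' at 0.5). Folds are stratified by class. Per-trial error is the mean over
#' folds; `mean_error` averages the `n_trials` trial errors and `se` is
#' their standard error, matching the averaged-error-curve selection rule.
#'
#' @inheritParams rank_features
#' @param ranked_features Character vector of feature ids, most important
#'   first (see [rank_features()]).
#' @param counts Increasing integer marker counts to sweep (default: a
#'   log-spaced grid up to all features).
#' @param n_trials Number of repeated cross-validations (default 5).
#' @param n_folds Folds per trial (default 10).
#' @return Tibble of class `error_curve`: `marker_count`, `mean_error`,
#'   `se`, plus attributes `n_trials`, `n_folds`.
#' @export
cv_error_curve <- function(data, y, ranked_features, counts = NULL,
                           n_trials = 5, n_folds = 10, ntree = 500,
                           seed = 1L) {
  m <- ft_matrix(data)
  enc <- encode_labels(y)
  stopifnot(all(ranked_features %in% colnames(m)))
  p <- length(ranked_features)
  if (is.null(counts)) {
    counts <- unique(pmin(p, c(2^(0:ceiling(log2(p))), p)))
  }
  counts <- sort(unique(as.integer(counts)))
  if (any(counts < 1) || any(counts > p)) {
    stop("counts must lie in [1, number of ranked features]", call. = FALSE)
  }
  trial_err <- matrix(NA_real_, n_trials, length(counts))
  for (trial in seq_len(n_trials)) {
    fold <- stratified_folds(enc$y01, n_folds,
                             derive_seed(seed, paste0("folds", trial)))
    fold_err <- matrix(NA_real_, n_folds, length(counts))
    for (k in seq_len(n_folds)) {
      test <- fold == k
      if (!any(test)) next
      for (ci in seq_along(counts)) {
        feats <- ranked_features[seq_len(counts[ci])]
        prob <- rf_predict_cpp(m[!test, feats, drop = FALSE],
                               enc$y01[!test],
                               m[test, feats, drop = FALSE],
                               as.integer(ntree), rf_mtry(counts[ci]), 1L,
                               derive_seed(seed, sprintf("t%df%dc%d", trial,
                                                         k, counts[ci])))
        fold_err[k, ci] <- mean((prob > 0.5) != enc$y01[test])
      }
    }
    trial_err[trial, ] <- colMeans(fold_err, na.rm = TRUE)
  }
  out <- tibble::tibble(
    marker_count = counts,
    mean_error = colMeans(trial_err),
    se = apply(trial_err, 2, sd) / sqrt(n_trials))
  class(out) <- c("error_curve", class(out))
  attr(out, "n_trials") <- n_trials
  attr(out, "n_folds") <- n_folds
  out
}

#' Minimum-plus-standard-error marker-count selection
#'
#' The cutoff is the minimum of the averaged error curve plus the standard
#' error at that point; the selected model is the smallest marker count
#' whose mean error is strictly below the cutoff. On a degenerate flat
#' curve (no count strictly below the cutoff) the count at the minimum is
#' returned with a warning.
#'
#' @param curve An `error_curve` from [cv_error_curve()].
#' @return The selected marker count (integer).
#' @export
select_markers <- function(curve) {
  if (!is.data.frame(curve) || nrow(curve) == 0) {
    stop("curve must be a nonempty error curve", call. = FALSE)
  }
  i_min <- which.min(curve$mean_error)
  cutoff <- curve$mean_error[i_min] + curve$se[i_min]
  below <- which(curve$mean_error < cutoff)
  if (length(below) == 0) {
    warning("flat error curve: no count strictly below the cutoff; using the minimum-error count")
    return(curve$marker_count[i_min])
  }
  curve$marker_count[min(below)]
}

#' ROC AUC with bootstrap confidence interval
#'
#' AUC by the rank (Mann-Whitney) formulation with midrank ties (tied
#' case/control score pairs count one half), equal to the fraction of
#' concordant case/control pairs. The 95% CI is a stratified bootstrap
#' percentile interval.
#'
#' @param scores Per-sample case scores or probabilities.
#' @param labels Binary labels (cases = the higher factor level).
#' @param n_boot Bootstrap resamples for the CI (default 2000; 0 skips it).
#' @param seed Integer seed for resampling.
#' @return One-row tibble: `auc`, `ci_lo`, `ci_hi`, `n_case`, `n_control`.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, seed = 1L) {
  enc <- encode_labels(labels)
  y <- enc$y01
  if (all(y == 1) || all(y == 0)) stop("both classes must be present")
  auc_of <- function(s, y) {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    r <- rank(s)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_of(scores, y)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    i1 <- which(y == 1); i0 <- which(y == 0)
    boots <- vapply(seq_len(n_boot), function(b) {
      j <- c(sample(i1, length(i1), replace = TRUE),
             sample(i0, length(i0), replace = TRUE))
      auc_of(scores[j], y[j])
    }, numeric(1))
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  tibble::tibble(auc = auc, ci_lo = ci[1], ci_hi = ci[2],
                 n_case = sum(y == 1), n_control = sum(y == 0))
}

#' Fit a random-forest marker model on a discovery cohort
#'
#' End-to-end marker selection: rank features by importance on the full
#' discovery data, sweep the averaged cross-validation error curve, select
#' the marker count by the minimum-plus-SE rule, then score the discovery
#' samples by cross-validated vote fractions restricted to the selected
#' markers and report AUC with a bootstrap CI.
#'
#' @inheritParams cv_error_curve
#' @param n_boot Bootstrap resamples for the AUC CI.
#' @return An object of class `marker_model`: list with
#'   `selected_features`, `n_selected`, `auc`, `auc_ci`, `cohort`
#'   (`"discovery"`), `curve`, `ranking`, `scores` (tibble of per-sample
#'   cross-validated scores) and the training data needed for
#'   [evaluate_on_cohort()].
#' @export
fit_marker_model <- function(data, y, counts = NULL, n_trials = 5,
                             n_folds = 10, ntree = 500, n_boot = 2000,
                             seed = 1L) {
  m <- ft_matrix(data)
  enc <- encode_labels(y)
  ranking <- rank_features(data, y, ntree = ntree,
                           seed = derive_seed(seed, "rank"))
  curve <- cv_error_curve(data, y, ranking$feature_id, counts = counts,
                          n_trials = n_trials, n_folds = n_folds,
                          ntree = ntree, seed = derive_seed(seed, "curve"))
  n_sel <- select_markers(curve)
  feats <- ranking$feature_id[seq_len(n_sel)]
  # cross-validated discovery scores on the selected panel
  fold <- stratified_folds(enc$y01, n_folds, derive_seed(seed, "scorefolds"))
  prob <- rep(NA_real_, nrow(m))
  for (k in sort(unique(fold))) {
    test <- fold == k
    prob[test] <- rf_predict_cpp(m[!test, feats, drop = FALSE],
                                 enc$y01[!test],
                                 m[test, feats, drop = FALSE],
                                 as.integer(ntree), rf_mtry(n_sel), 1L,
                                 derive_seed(seed, paste0("score", k)))
  }
  a <- roc_auc(prob, enc$y01, n_boot = n_boot,
               seed = derive_seed(seed, "auc"))
  structure(list(selected_features = feats, n_selected = n_sel,
                 auc = a$auc, auc_ci = c(a$ci_lo, a$ci_hi),
                 cohort = "discovery", curve = curve, ranking = ranking,
                 scores = tibble::tibble(sample_id = rownames(m),
                                         label = enc$y01, score = prob),
                 train = list(X = m[, feats, drop = FALSE], y = enc$y01,
                              ntree = ntree, seed = derive_seed(seed, "fit"),
                              levels = enc$levels),
                 n_boot = n_boot),
            class = "marker_model")
}

#' Evaluate a marker model on a validation cohort
#'
#' Refits the forest on the discovery samples restricted to the selected
#' markers and scores the validation samples; AUC and CI are computed on
#' the validation labels.
#'
#' @param model A `marker_model` from [fit_marker_model()].
#' @param data_validation Validation feature tibble; must contain every
#'   selected feature.
#' @param y_validation Binary validation labels.
#' @return A `marker_model` tagged `cohort = "validation"`.
#' @export
evaluate_on_cohort <- function(model, data_validation, y_validation) {
  stopifnot(inherits(model, "marker_model"))
  mv <- ft_matrix(data_validation, "data_validation")
  missing <- setdiff(model$selected_features, colnames(mv))
  if (length(missing) > 0) {
    stop(sprintf("validation table is missing selected feature '%s'",
                 missing[1]), call. = FALSE)
  }
  enc <- encode_labels(y_validation)
  prob <- rf_predict_cpp(model$train$X, model$train$y,
                         mv[, model$selected_features, drop = FALSE],
                         as.integer(model$train$ntree),
                         rf_mtry(model$n_selected), 1L,
                         as.integer(model$train$seed))
  a <- roc_auc(prob, enc$y01, n_boot = model$n_boot,
               seed = derive_seed(model$train$seed, "vauc"))
  out <- model
  out$cohort <- "validation"
  out$auc <- a$auc
  out$auc_ci <- c(a$ci_lo, a$ci_hi)
  out$scores <- tibble::tibble(sample_id = rownames(mv), label = enc$y01,
                               score = prob)
  out
}
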