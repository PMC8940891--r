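sim_marker_data <- function(n = 60, p = 20, informative = 2, shift = 1.5,
                            seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("f%02d", 1:p)))
  for (j in seq_len(informative)) m[, j] <- m[, j] + shift * y
  list(data = as_ft(m), y = y)
}

test_that("importance ranking puts informative features first", {
  top_hits <- vapply(1:10, function(sd) {
    d <- sim_marker_data(informative = 1, shift = 2, seed = sd)
    rank_features(d$data, d$y, ntree = 200, seed = sd)$feature_id[1] == "f01"
  }, logical(1))
  expect_gte(mean(top_hits), 0.95)
  # a duplicated informative feature occupies the top two ranks
  d <- sim_marker_data(informative = 1, shift = 2, seed = 3)
  d2 <- dplyr::mutate(d$data, f21 = .data$f01 + rnorm(60, sd = 0.01))
  rk <- rank_features(d2, d$y, ntree = 500, seed = 5)
  expect_setequal(rk$feature_id[1:2], c("f01", "f21"))
  # deterministic given the seed
  expect_identical(rank_features(d$data, d$y, seed = 7),
                   rank_features(d$data, d$y, seed = 7))
  expect_error(rank_features(d$data, rep(1, 60)), "two classes")
})

test_that("cv_error_curve behaves at the extremes and is deterministic", {
  # a perfectly separating feature: error ~ 0 at c = 1
  d <- sim_marker_data(informative = 1, shift = 6, seed = 11)
  curve <- cv_error_curve(d$data, d$y, ranked_features = c("f01", "f02"),
                          counts = c(1, 2), n_trials = 2, n_folds = 5,
                          ntree = 100, seed = 1)
  expect_lt(curve$mean_error[1], 0.05)
  # labels independent of X: error around 0.5
  dn <- sim_marker_data(informative = 0, seed = 12)
  curven <- cv_error_curve(dn$data, dn$y,
                           ranked_features = sprintf("f%02d", 1:20),
                           counts = c(2, 10), n_trials = 2, n_folds = 5,
                           ntree = 100, seed = 2)
  expect_true(all(abs(curven$mean_error - 0.5) < 0.12))
  # determinism contract
  expect_identical(curven,
                   cv_error_curve(dn$data, dn$y,
                                  ranked_features = sprintf("f%02d", 1:20),
                                  counts = c(2, 10), n_trials = 2,
                                  n_folds = 5, ntree = 100, seed = 2))
  expect_error(cv_error_curve(dn$data, dn$y, sprintf("f%02d", 1:20),
                              counts = c(0, 5)), "counts")
})

test_that("select_markers applies the minimum-plus-SE rule", {
  curve <- tibble::tibble(marker_count = c(1L, 2L, 4L, 8L),
                          mean_error = c(0.40, 0.20, 0.20, 0.21),
                          se = c(0.05, 0.02, 0.03, 0.02))
  # cutoff = 0.20 + 0.02 = 0.22; the first count strictly below is 2
  expect_equal(select_markers(curve), 2L)
  # monotone-decreasing curve with zero SE selects the argmin count
  # (via the degenerate-cutoff fallback, since nothing is strictly below)
  curve2 <- tibble::tibble(marker_count = c(1L, 2L, 4L),
                           mean_error = c(0.5, 0.3, 0.1), se = c(0, 0, 0))
  expect_equal(suppressWarnings(select_markers(curve2)), 4L)
  # flat curve: fall back to the argmin with a warning
  curve3 <- tibble::tibble(marker_count = c(1L, 2L),
                           mean_error = c(0.3, 0.3), se = c(0, 0))
  expect_warning(sel <- select_markers(curve3), "flat")
  expect_equal(sel, 1L)
  # appending larger counts with higher error changes nothing
  curve4 <- dplyr::bind_rows(curve, tibble::tibble(
    marker_count = c(16L, 32L), mean_error = c(0.3, 0.35), se = c(0, 0)))
  expect_equal(select_markers(curve4), select_markers(curve))
  expect_error(select_markers(tibble::tibble()), "nonempty")
})

test_that("AUC equals the all-pairs concordance fraction", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                       n_boot = 0)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5), n_boot = 0)$auc, 0.5)
  set.seed(13)
  for (i in 1:10) {
    s <- sample(seq(0, 1, by = 0.05), 40, replace = TRUE)  # with ties
    y <- rep(c(0, 1), each = 20)
    expect_equal(roc_auc(s, y, n_boot = 0)$auc, oracle_auc(s, y),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "class")
})

test_that("bootstrap CI brackets the AUC and is seed-stable", {
  set.seed(14)
  s <- c(rnorm(30, 1), rnorm(30))
  y <- rep(c(1, 0), each = 30)
  a1 <- roc_auc(s, y, n_boot = 500, seed = 9)
  a2 <- roc_auc(s, y, n_boot = 500, seed = 9)
  expect_identical(a1, a2)
  expect_lte(a1$ci_lo, a1$auc)
  expect_gte(a1$ci_hi, a1$auc)
})

test_that("marker models generalize to validation cohorts of the same process", {
  d <- sim_marker_data(n = 80, p = 15, informative = 3, shift = 1.2, seed = 21)
  model <- fit_marker_model(d$data, d$y, counts = c(1, 3, 8, 15),
                            n_trials = 2, n_folds = 5, ntree = 150,
                            n_boot = 200, seed = 4)
  expect_gte(model$auc, 0.85)
  expect_true(all(model$selected_features %in% sprintf("f%02d", 1:15)))
  v <- sim_marker_data(n = 80, p = 15, informative = 3, shift = 1.2, seed = 22)
  val <- evaluate_on_cohort(model, v$data, v$y)
  expect_equal(val$cohort, "validation")
  expect_lt(abs(val$auc - model$auc), 0.15)
  # repeat evaluation is deterministic
  val2 <- evaluate_on_cohort(model, v$data, v$y)
  expect_identical(val$auc, val2$auc)
  # permuted validation labels: chance-level AUC
  set.seed(5)
  valp <- evaluate_on_cohort(model, v$data, sample(v$y))
  expect_lt(abs(valp$auc - 0.5), 0.2)
  dropped <- dplyr::select(d$data,
                           -dplyr::all_of(model$selected_features[1]))
  expect_error(evaluate_on_cohort(model, dropped, d$y), "missing")
  # broom-style accessors
  expect_equal(nrow(tidy(model)), model$n_selected)
  expect_equal(glance(model)$auc, model$auc)
})
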