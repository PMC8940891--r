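test_that("smooth_zeros replaces zeros with half the per-sample minimum", {
  m <- rbind(S1 = c(0, 2, 4), S2 = c(1, 2, 3))
  colnames(m) <- paste0("f", 1:3)
  out <- ft_mat <- as.matrix(smooth_zeros(as_ft(m))[-1])
  expect_equal(unname(out[1, ]), c(1, 2, 4))
  expect_equal(unname(out[2, ]), c(1, 2, 3))  # untouched
  # mixed table against a row-wise oracle
  set.seed(61)
  m2 <- matrix(rexp(20), 5, 4,
               dimnames = list(paste0("S", 1:5), paste0("f", 1:4)))
  m2[sample(20, 6)] <- 0
  sm <- as.matrix(smooth_zeros(as_ft(m2))[-1])
  for (i in 1:5) {
    expected <- m2[i, ]
    expected[expected == 0] <- min(expected[expected > 0]) / 2
    expect_equal(unname(sm[i, ]), unname(expected))
  }
  expect_true(all(sm > 0))
  m2[2, ] <- 0
  expect_error(smooth_zeros(as_ft(m2)), "S2")
})

test_that("log_transform is the natural log with positivity enforcement", {
  m <- rbind(S1 = c(1, exp(1)))
  colnames(m) <- c("a", "b")
  out <- as.matrix(log_transform(as_ft(m))[-1])
  expect_equal(unname(out[1, ]), c(0, 1))
  set.seed(1)
  m2 <- matrix(rexp(12) + 0.1, 3, 4,
               dimnames = list(paste0("S", 1:3), paste0("f", 1:4)))
  round_trip <- exp(as.matrix(log_transform(as_ft(m2))[-1]))
  expect_equal(unname(round_trip), unname(m2), tolerance = 1e-12)
  m2[1, 1] <- 0
  expect_error(log_transform(as_ft(m2)), "smooth_zeros")
})

test_that("residualize removes phenotype and age structure", {
  set.seed(71)
  n <- 300
  md <- tibble::tibble(sample_id = sprintf("S%03d", 1:n),
                       group = rep(c("IBS", "HC"), each = n / 2),
                       age = runif(n, 18, 65))
  ind <- as.numeric(md$group == "IBS")
  m <- cbind(pure_group = 2 + 3 * ind,
             age_driven = 0.3 * md$age + rnorm(n),
             noise = rnorm(n))
  rownames(m) <- md$sample_id
  res <- residualize(as_ft(m), md)
  rm_ <- as.matrix(res[-1])
  expect_lt(max(abs(rm_[, "pure_group"])), 1e-10)
  expect_lt(abs(cor(rm_[, "age_driven"], md$age)), 0.05)
  expect_true(all(abs(colMeans(rm_)) < 1e-8))
})

test_that("residuals match the explicit hat-matrix computation", {
  set.seed(72)
  n <- 10
  md <- tibble::tibble(sample_id = paste0("S", 1:n),
                       group = rep(c("IBS", "HC"), each = 5),
                       age = runif(n, 20, 60))
  m <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(md$sample_id, paste0("f", 1:3)))
  res <- as.matrix(residualize(as_ft(m), md)[-1])
  X <- cbind(1, md$group == "IBS", md$age)
  for (j in 1:3) {
    expect_equal(unname(res[, j]), oracle_ols_residuals(X, m[, j]),
                 tolerance = 1e-10)
  }
  # constant age is collinear with the intercept -> rank-deficient design
  md_bad <- dplyr::mutate(md, age = 50)
  expect_error(residualize(as_ft(m), md_bad), "rank-deficient")
  # single-level phenotype rejected
  expect_error(residualize(as_ft(m), dplyr::mutate(md, group = "IBS")),
               "2 levels")
})

test_that("greedy_cluster follows the sequential rule and renumbers by size", {
  set.seed(81)
  n <- 60
  f <- rnorm(n)
  # f1, f2 strongly correlated; f3 weakly related to both
  m <- cbind(f1 = f + rnorm(n, sd = 0.25),
             f2 = f + rnorm(n, sd = 0.25),
             f3 = 0.5 * f + rnorm(n))
  rownames(m) <- paste0("S", 1:n)
  rmat <- cor(m, method = "spearman")
  # guard the construction: pair above threshold, f3 below with both
  expect_gt(rmat["f1", "f2"], 0.7)
  expect_lt(mean(rmat["f3", c("f1", "f2")]), 0.7)
  asg <- greedy_cluster(as_ft(m), ranking = c("f1", "f2", "f3"))
  expect_equal(asg$cluster[match(c("f1", "f2", "f3"), asg$feature_id)],
               c(1L, 1L, 2L))
  expect_equal(sum(asg$is_seed), 2)
  # identical rank order joins immediately
  m2 <- cbind(a = 1:10, b = exp(1:10))
  rownames(m2) <- paste0("S", 1:10)
  asg2 <- greedy_cluster(as_ft(m2))
  expect_equal(unique(asg2$cluster), 1L)
  expect_error(greedy_cluster(as_ft(m2), r_threshold = 1.2), "-1, 1")
  expect_error(greedy_cluster(as_ft(m2), ranking = c("a", "zzz")),
               "permutation")
})

test_that("greedy_cluster agrees with the naive oracle and is a partition", {
  set.seed(82)
  for (rep_i in 1:5) {
    n <- 40; p <- 30
    base <- matrix(rnorm(n * 3), n, 3)
    load <- base[, sample(3, p, replace = TRUE)]
    m <- load * runif(p, 0.4, 1)[col(load)] + matrix(rnorm(n * p), n, p)
    colnames(m) <- sprintf("f%02d", 1:p)
    rownames(m) <- sprintf("S%02d", 1:n)
    ranking <- sample(colnames(m))
    asg <- greedy_cluster(as_ft(m), ranking, r_threshold = 0.4)
    oracle <- oracle_greedy_cluster(m, ranking, 0.4)
    expect_equal(asg$cluster[match(names(oracle), asg$feature_id)],
                 unname(oracle))
    # partition property and size ordering
    expect_setequal(asg$feature_id, colnames(m))
    expect_equal(anyDuplicated(asg$feature_id), 0L)
    sizes <- as.integer(table(asg$cluster))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("raising the threshold never merges clusters", {
  set.seed(83)
  n <- 30; p <- 15
  m <- matrix(rnorm(n * p), n, p) + rnorm(n)
  colnames(m) <- sprintf("f%02d", 1:p)
  rownames(m) <- sprintf("S%02d", 1:n)
  ranking <- colnames(m)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th) {
    max(greedy_cluster(as_ft(m), ranking, r_threshold = th)$cluster)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # determinism under a fixed ranking
  expect_identical(greedy_cluster(as_ft(m), ranking, r_threshold = 0.4),
                   greedy_cluster(as_ft(m), ranking, r_threshold = 0.4))
})

test_that("cluster_summary tabulates directions per cluster", {
  asg <- greedy_cluster(as_ft(cbind(S1 = c(1, 2), S2 = c(2, 3), S3 = c(3, 4)) |>
    t() |> (\(x) {colnames(x) <- c("a", "b"); x})()))
  diffs <- tibble::tibble(feature_id = c("a", "b"),
                          direction = c("case_enriched", "case_enriched"))
  s <- cluster_summary(asg, diffs)
  expect_equal(s$majority_direction, "case_enriched")
  expect_equal(s$unanimity, 1)
  expect_error(cluster_summary(asg, diffs[1, ]), "not present")
  empty <- cluster_summary(
    structure(tibble::tibble(feature_id = character(), cluster = integer(),
                             is_seed = logical()),
              class = c("cluster_assignment", "tbl_df", "tbl", "data.frame")),
    diffs)
  expect_equal(nrow(empty), 0)
})

test_that("planted clusters are recovered from residual abundances", {
  cfg <- synth_config(n_case = 60, n_control = 60, n_species = 20,
                      n_metabolites = 100, frac_differential = 0.3,
                      cluster_sizes = c(10L, 5L), cluster_corr = 0.9,
                      n_associations = 0, seed = 31)
  co <- generate_cohort(cfg)
  truth <- co$truth$cluster_membership
  resid <- residualize(log_transform(smooth_zeros(co$fecal_mets)),
                       co$metadata)
  planted_tbl <- dplyr::select(resid, "sample_id",
                               dplyr::all_of(truth$feature_id))
  asg <- greedy_cluster(planted_tbl)
  got <- asg$cluster[match(truth$feature_id, asg$feature_id)]
  expect_gte(adjusted_rand_index(got, truth$cluster), 0.8)
  # sizes recovered in order (largest first)
  s <- cluster_summary(asg, differential_features(co$fecal_mets, co$metadata))
  expect_equal(s$size[1:2], c(10L, 5L))
})
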