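test_that("wilcoxon_rank_sum handles exact and approximate regimes", {
  # identical multisets: exact p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(3, 1, 2))$p_value, 1)
  # fully separated small groups: U = 0, exact two-sided p = 2/20
  res <- wilcoxon_rank_sum(1:3, 4:6)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_error(wilcoxon_rank_sum(1:2, 4:6), "at least 3")
  # large shifted normals are detected essentially always
  set.seed(31)
  hits <- vapply(1:10, function(i) {
    wilcoxon_rank_sum(rnorm(60), rnorm(60) + 1)$p_value < 1e-3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("exact Wilcoxon p equals full labeling enumeration for small groups", {
  set.seed(17)
  for (i in 1:10) {
    a <- round(rnorm(sample(3:6, 1)), 4)
    b <- round(rnorm(sample(3:6, 1)) + runif(1, -1, 1), 4)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 oracle_wilcoxon_exact_p(a, b), tolerance = 1e-12)
  }
})

test_that("bh_fdr implements step-up BH", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("fold_change is the raw-scale mean ratio", {
  expect_equal(fold_change(c(1, 3), c(2, 2)), 1)
  expect_equal(fold_change(c(2, 2), c(1, 1)), 2)
  expect_warning(fc <- fold_change(c(1, 2), c(0, 0)), "undefined")
  expect_true(is.na(fc))
})

test_that("VIP scores satisfy the algebraic identities", {
  set.seed(51)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  # identical copies of the signal: all VIP = 1
  sig <- y + rnorm(n, sd = 0.3)
  Xc <- matrix(rep(sig, 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  vc <- plsda_vip(Xc, y, n_components = 1)
  expect_equal(unname(vc), rep(1, 6), tolerance = 1e-8)
  # mean squared VIP = 1 on arbitrary fits
  for (i in 1:5) {
    X <- matrix(rnorm(n * 12), n)
    X[, 1] <- X[, 1] + y
    v <- plsda_vip(X, y, n_components = 2)
    expect_equal(mean(v^2), 1, tolerance = 1e-8)
  }
  # single informative feature among noise: VIP -> sqrt(p)
  p <- 25
  X1 <- matrix(rnorm(2000 * p), 2000)
  y1 <- rep(c(0, 1), each = 1000)
  X1[, 1] <- y1 + rnorm(2000, sd = 0.05)
  v1 <- plsda_vip(X1, y1, n_components = 1)
  expect_gt(v1[1], 0.95 * sqrt(p))
  expect_error(plsda_vip(X1, rep(1, 2000)), "two classes")
})

test_that("VIP is invariant to feature scaling and label swapping", {
  set.seed(52)
  n <- 60
  X <- matrix(rnorm(n * 8), n)
  y <- rep(c("a", "b"), each = n / 2)
  X[, 2] <- X[, 2] + (y == "b")
  v0 <- plsda_vip(X, y)
  v_scaled <- plsda_vip(sweep(X, 2, c(1e3, 1e-3, rep(1, 6)), `*`), y)
  v_swapped <- plsda_vip(X, rev(y)[order(seq_len(n))] |>
                           (\(z) ifelse(y == "a", "b", "a"))())
  expect_equal(v0, v_scaled, tolerance = 1e-8)
  expect_equal(v0, v_swapped, tolerance = 1e-8)
})

test_that("differential_features recovers planted effects and sets flags consistently", {
  cfg <- synth_config(n_case = 60, n_control = 60, n_species = 30,
                      n_metabolites = 100, frac_differential = 0.1,
                      cluster_sizes = integer(0), n_associations = 0,
                      log_fold_effect = log(2), seed = 13)
  co <- generate_cohort(cfg)
  crit <- criteria_config(mode = "combined")
  d <- differential_features(co$fecal_mets, co$metadata, crit)
  truth <- co$truth$differential_ids
  planted <- truth$feature_id[truth$table == "fecal"]
  hits <- d$feature_id[d$passes_univariate]
  expect_gte(mean(planted %in% hits), 0.8)
  # flags recompute from the columns
  expect_equal(d$passes_combined,
               d$q_value < 0.1 & d$vip > 1 &
                 (d$fold_change <= 0.8 | d$fold_change >= 1.2))
  expect_equal(d$passes_univariate, d$q_value < 0.1)
  expect_equal(d$direction,
               ifelse(d$fold_change >= 1, "case_enriched",
                      "control_enriched"))
  expect_true(all(d$q_value >= d$p_value - 1e-12))
  # ordered by ascending q then id
  expect_false(is.unsorted(d$q_value))
})

test_that("differential_features is invariant to sample and feature order", {
  cfg <- synth_config(n_case = 15, n_control = 12, n_species = 10,
                      n_metabolites = 30, frac_differential = 0.2,
                      cluster_sizes = integer(0), n_associations = 0,
                      seed = 19)
  co <- generate_cohort(cfg)
  d0 <- differential_features(co$fecal_mets, co$metadata)
  set.seed(1)
  shuf <- co$fecal_mets[sample(nrow(co$fecal_mets)),
                        c(1, 1 + sample(30))]
  d1 <- differential_features(shuf, co$metadata)
  expect_equal(d0, d1, ignore_attr = TRUE)
  expect_error(
    differential_features(co$fecal_mets[c(1, 2, 16:20), ], co$metadata),
    "3 samples")
})

test_that("null tables yield no univariate discoveries most of the time", {
  hits <- vapply(1:10, function(sd) {
    co <- generate_cohort(synth_config(
      n_case = 30, n_control = 30, n_species = 10, n_metabolites = 60,
      frac_differential = 0, cluster_sizes = integer(0),
      n_associations = 0, seed = 100 + sd))
    d <- differential_features(co$fecal_mets, co$metadata)
    sum(d$passes_univariate)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})
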