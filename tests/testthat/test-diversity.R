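test_that("Shannon index matches the -sum(p log p) definition", {
  m <- rbind(S1 = c(5, 0, 0, 0), S2 = c(1, 1, 1, 1), S3 = c(1, 2, 3, 0))
  colnames(m) <- paste0("f", 1:4)
  h <- shannon_index(as_ft(m))
  expect_equal(h$shannon[1], 0)
  expect_equal(h$shannon[2], log(4))
  p <- c(1, 2, 3) / 6
  expect_equal(h$shannon[3], -sum(p * log(p)))
  m[2, ] <- 0
  expect_error(shannon_index(as_ft(m)), "S2")
  # richness counts detected features
  a <- alpha_diversity(as_ft(rbind(S1 = c(1, 0, 2), S2 = c(1, 1, 1))))
  expect_equal(a$richness, c(2L, 3L))
})

test_that("Bray-Curtis distances follow the formula", {
  m <- rbind(u = c(1, 0, 1), v = c(0, 1, 1), w = c(1, 0, 1),
             x = c(2, 0, 0), y = c(0, 3, 0))
  colnames(m) <- paste0("f", 1:3)
  d <- as.matrix(bray_curtis(as_ft(m)))
  expect_equal(d["u", "v"], 0.5)       # |1-0|+|0-1|+0 over 4
  expect_equal(d["u", "w"], 0)         # identical samples
  expect_equal(d["x", "y"], 1)         # disjoint supports
  expect_true(all(abs(d - t(d)) < 1e-12))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PCoA reproduces Euclidean configurations", {
  set.seed(4)
  pts <- matrix(rnorm(20), 10, 2)
  d <- dist(pts)
  attr(d, "Labels") <- paste0("S", 1:10)
  ord <- pcoa_ordination(d, k = 2)
  emb <- as.matrix(ord$scores[, c("Axis1", "Axis2")])
  expect_equal(as.numeric(dist(emb)), as.numeric(d), tolerance = 1e-6)
  expect_true(all(ord$variance_explained > 0))
  # three equidistant points: two equal positive eigenvalues
  d3 <- as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  ord3 <- pcoa_ordination(d3, k = 2)
  pos <- ord3$eigenvalues[ord3$eigenvalues > 1e-8]
  expect_equal(pos[1], pos[2], tolerance = 1e-10)
})

test_that("permanova matches vegan::adonis2 on R^2 and F", {
  set.seed(9)
  m <- matrix(rexp(30 * 8), 30, 8,
              dimnames = list(paste0("S", 1:30), paste0("f", 1:8)))
  g <- rep(c("a", "b", "c"), each = 10)
  md <- tibble::tibble(sample_id = rownames(m), grp = g,
                       num = rnorm(30))
  d <- bray_curtis(as_ft(m))
  res <- permanova(d, md, "grp", n_permutations = 999, seed = 1)
  ad <- vegan::adonis2(d ~ grp, data = data.frame(grp = g),
                       permutations = 99)
  expect_equal(res$r_squared, ad$R2[1], tolerance = 1e-10)
  expect_equal(res$f_statistic, ad$F[1], tolerance = 1e-10)
  # classical within/among decomposition oracle agrees too
  or <- oracle_permanova_f(as.matrix(d), g)
  expect_equal(res$f_statistic, or$f, tolerance = 1e-10)
  expect_equal(res$r_squared, or$r_squared, tolerance = 1e-10)
  # numeric factors run through the one-predictor pseudo-F path
  resn <- permanova(d, md, "num", n_permutations = 99, seed = 1)
  adn <- vegan::adonis2(d ~ num, data = data.frame(num = md$num),
                        permutations = 9)
  expect_equal(resn$r_squared, adn$R2[1], tolerance = 1e-10)
})

test_that("permanova permutation p is calibrated against enumeration at n=6", {
  set.seed(12)
  m <- matrix(rexp(6 * 5), 6, 5,
              dimnames = list(paste0("S", 1:6), paste0("f", 1:5)))
  g <- rep(c("a", "b"), each = 3)
  md <- tibble::tibble(sample_id = rownames(m), grp = g)
  d <- bray_curtis(as_ft(m))
  dm <- as.matrix(d)
  # exact permutation distribution over all 720 label orders
  perms <- gtools_permutations(6)
  f_obs <- oracle_permanova_f(dm, g)$f
  fs <- apply(perms, 1, function(p) oracle_permanova_f(dm, g[p])$f)
  p_exact <- mean(fs >= f_obs - 1e-10)
  res <- permanova(d, md, "grp", n_permutations = 2000, seed = 7)
  # Monte-Carlo estimate within 3 binomial SEs of the exact value
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 2 / 2001)
})

test_that("perfect group separation gives R^2 near 1 and the minimal p", {
  base <- rbind(matrix(rep(c(10, 0, 0), each = 10), 10),
                matrix(rep(c(0, 10, 5), each = 10), 10))
  rownames(base) <- paste0("S", 1:20)
  colnames(base) <- paste0("f", 1:3)
  g <- rep(c("a", "b"), each = 10)
  md <- tibble::tibble(sample_id = rownames(base), grp = g)
  res <- permanova(bray_curtis(as_ft(base)), md, "grp",
                   n_permutations = 1000, seed = 2)
  expect_gt(res$r_squared, 0.99)
  expect_equal(res$p_value, 1 / 1001)
})

test_that("permanova rejects degenerate factors", {
  m <- matrix(rexp(8 * 4), 8, 4,
              dimnames = list(paste0("S", 1:8), paste0("f", 1:4)))
  d <- bray_curtis(as_ft(m))
  md <- tibble::tibble(sample_id = rownames(m),
                       solo = c("a", rep("b", 7)),
                       flat = rep("x", 8))
  expect_error(permanova(d, md, "solo"), "fewer than 2")
  expect_error(permanova(d, md, "flat"), "single level")
})

test_that("factor_screen orders by R^2, BH-adjusts and handles missing values", {
  set.seed(21)
  # a strong planted effect so the group factor clearly leads the screen
  cfg <- synth_config(n_case = 40, n_control = 40, n_species = 40,
                      n_metabolites = 30, cluster_sizes = integer(0),
                      n_associations = 0, frac_differential = 0.3,
                      log_fold_effect = log(6), seed = 8)
  co <- generate_cohort(cfg)
  d <- bray_curtis(filter_species(co$microbiome))
  md <- co$metadata
  md$noise <- rnorm(nrow(md))
  md$noise[1:5] <- NA
  scr <- factor_screen(d, md, c("group", "noise", "age"),
                       n_permutations = 199, seed = 3)
  expect_equal(scr$factor[1], "group")  # the planted effect dominates
  expect_true(all(diff(scr$r_squared) <= 0))
  expect_true(all(scr$q_value >= scr$p_value - 1e-12))
  expect_equal(scr$n_samples[scr$factor == "noise"], 75)
  one <- factor_screen(d, md, "group", n_permutations = 99, seed = 3)
  expect_equal(one$q_value, one$p_value)
  expect_error(factor_screen(d, md, character(0)), "at least one")
})

test_that("spearman_cor matches exact enumeration at n=5 and flags degeneracy", {
  x <- c(3, 1, 4, 1.5, 9)
  y <- c(2, 7, 1, 8, 3)
  res <- spearman_cor(x, y)
  expect_equal(res$p_value, oracle_spearman_exact_p(x, y), tolerance = 1e-12)
  expect_equal(spearman_cor(1:10, exp(1:10))$estimate, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$estimate, -1)
  expect_warning(res0 <- spearman_cor(rep(1, 5), 1:5), "rank variance")
  expect_true(res0$degenerate)
})

test_that("beta dispersion compares distance-to-centroid between groups", {
  set.seed(5)
  m <- rbind(matrix(rexp(10 * 6), 10),          # tight group
             matrix(rexp(10 * 6) * 5, 10))      # dispersed group
  rownames(m) <- paste0("S", 1:20)
  colnames(m) <- paste0("f", 1:6)
  md <- tibble::tibble(sample_id = rownames(m),
                       group = rep(c("HC", "IBS"), each = 10))
  bd <- beta_dispersion(bray_curtis(as_ft(m)), md)
  expect_equal(nrow(bd$dispersion), 20)
  expect_true(bd$p_value >= 0 && bd$p_value <= 1)
})
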