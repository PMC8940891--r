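# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with the package: plain
# loops and first-principles definitions only.

# Feature tibble from a plain matrix (rownames = sample ids).
as_ft <- function(m) {
  df <- as.data.frame(m)
  df <- cbind(sample_id = rownames(m), df)
  tibble::as_tibble(df)
}

# Naive sequential covariation clustering: scan features in ranking order,
# join the first cluster (creation order) whose members' mean Spearman
# correlation with the candidate strictly exceeds the threshold, else open a
# new cluster; renumber by size descending, earlier-created first on ties.
oracle_greedy_cluster <- function(resmat, ranking, threshold) {
  members <- list()
  for (f in ranking) {
    placed <- FALSE
    for (ci in seq_along(members)) {
      sims <- numeric(0)
      for (g in members[[ci]]) {
        sims <- c(sims, cor(resmat[, f], resmat[, g], method = "spearman"))
      }
      if (mean(sims) > threshold) {
        members[[ci]] <- c(members[[ci]], f)
        placed <- TRUE
        break
      }
    }
    if (!placed) members[[length(members) + 1]] <- f
  }
  sizes <- vapply(members, length, integer(1))
  new_order <- order(-sizes, seq_along(members))
  out <- integer(0)
  for (rank_i in seq_along(new_order)) {
    for (g in members[[new_order[rank_i]]]) out[g] <- rank_i
  }
  out
}

# Step-up Benjamini-Hochberg from the definition: sort p ascending, q_(i) =
# min_{j >= i} p_(j) * m / j, clip at 1, return in input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- ps[i:m] * m / (i:m)
    q[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# AUC as the fraction of concordant case/control score pairs, ties half.
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cs) * length(ct))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n, n_a) group labelings of the pooled sample (no ties assumed);
# doubling rule on the smaller tail, as in the exact test.
oracle_wilcoxon_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact two-sided Spearman p by enumerating all permutations of y's ranks.
oracle_spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  perms <- gtools_permutations(n)
  rho_obs <- cor(rx, rank(y))
  rhos <- apply(perms, 1, function(p) cor(rx, p))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# All permutations of 1..n (small n only), no external dependency.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1
    }
  }
  out
}

# OLS residuals via the explicit hat matrix I - X (X'X)^-1 X'.
oracle_ols_residuals <- function(X, y) {
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  drop((diag(nrow(X)) - H) %*% y)
}

# Pseudo-F and R^2 for a grouping factor from the within/among distance
# decomposition (the classical PERMANOVA identity).
oracle_permanova_f <- function(dmat, groups) {
  n <- nrow(dmat)
  sst <- sum(dmat[upper.tri(dmat)]^2) / n
  ssw <- 0
  for (g in unique(groups)) {
    ix <- which(groups == g)
    sub <- dmat[ix, ix, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]^2) / length(ix)
  }
  ssa <- sst - ssw
  a <- length(unique(groups))
  f <- (ssa / (a - 1)) / (ssw / (n - a))
  list(f = f, r_squared = ssa / sst)
}
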