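#' Shannon diversity per sample
#'
#' Natural-log Shannon index `H = -sum(p_i log p_i)` over the within-sample
#' proportions of features with positive abundance.
#'
#' @param data Feature tibble with non-negative values and a positive total
#'   per sample.
#' @return Tibble with `sample_id` and `shannon`.
#' @export
shannon_index <- function(data) {
  m <- ft_matrix(data)
  check_nonnegative(m)
  if (any(rowSums(m) <= 0)) {
    stop(sprintf("sample '%s' is all zero; Shannon index undefined",
                 rownames(m)[which(rowSums(m) <= 0)[1]]), call. = FALSE)
  }
  tibble::tibble(sample_id = rownames(m),
                 shannon = as.numeric(vegan::diversity(m, index = "shannon")))
}

#' Alpha diversity summary (Shannon and richness)
#'
#' Richness is the count of features with positive abundance; for metabolome
#' intensity tables it is the detected-feature count.
#'
#' @inheritParams shannon_index
#' @return Tibble with `sample_id`, `shannon`, `richness`.
#' @export
alpha_diversity <- function(data) {
  m <- ft_matrix(data)
  shannon_index(data) |>
    dplyr::mutate(richness = as.integer(rowSums(m > 0)))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)` between sample pairs. A
#' pair of all-zero samples has undefined dissimilarity and is set to 0 with
#' a warning.
#'
#' @inheritParams shannon_index
#' @return A `dist` object labelled by sample id.
#' @export
bray_curtis <- function(data) {
  m <- ft_matrix(data)
  check_nonnegative(m)
  d <- vegan::vegdist(m, method = "bray")
  if (anyNA(d)) {
    warning("all-zero sample pair(s); their Bray-Curtis distance is set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: eigendecomposition of the Gower-centered
#' `-D^2/2`. Axes are ordered by eigenvalue and variance shares are
#' computed over positive eigenvalues only. If fewer than `k` positive
#' eigenvalues exist, the embedding is truncated with a warning.
#'
#' @param dist A `dist` object (e.g. from [bray_curtis()]).
#' @param k Number of axes requested.
#' @return An object of class `pcoa_ord`: list with `scores` (tibble:
#'   `sample_id`, `Axis1`, ...), `eigenvalues`, and `variance_explained`
#'   (shares of the positive-eigenvalue total for the returned axes).
#' @export
pcoa_ordination <- function(dist, k = 2) {
  stopifnot(inherits(dist, "dist"))
  n <- attr(dist, "Size")
  D2 <- as.matrix(dist)^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% D2 %*% C
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- which(eig$values > 1e-8 * max(abs(eig$values)))
  if (length(pos) < k) {
    warning(sprintf("only %d positive eigenvalues; returning %d axes",
                    length(pos), length(pos)))
    k <- length(pos)
  }
  scores <- eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(eig$values[pos[seq_len(k)]]), k, k)
  colnames(scores) <- paste0("Axis", seq_len(k))
  ids <- attr(dist, "Labels") %||% as.character(seq_len(n))
  structure(list(
    scores = tibble::as_tibble(as.data.frame(scores)) |>
      dplyr::mutate(sample_id = ids, .before = 1),
    eigenvalues = eig$values,
    variance_explained = eig$values[pos[seq_len(k)]] / sum(eig$values[pos])),
    class = "pcoa_ord")
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squares of a distance matrix by a single
#' metadata factor (categorical with >= 2 levels, or numeric treated as a
#' one-predictor linear term) and tests the pseudo-F statistic by permuting
#' sample identity. `p = (1 + #(F_perm >= F_obs)) / (1 + n_permutations)`.
#'
#' @param dist A `dist` object over the samples.
#' @param metadata Tibble with `sample_id` and the factor column; rows are
#'   matched to the distance labels. Samples missing the factor are dropped.
#' @param factor Name of the metadata column to test.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return One-row tibble: `factor`, `r_squared`, `f_statistic`, `p_value`,
#'   `n_permutations`, `n_samples`.
#' @export
permanova <- function(dist, metadata, factor, n_permutations = 1000,
                      seed = 1L) {
  stopifnot(inherits(dist, "dist"))
  if (!factor %in% names(metadata)) {
    stop(sprintf("factor '%s' not found in metadata", factor), call. = FALSE)
  }
  ids <- attr(dist, "Labels")
  md <- metadata[match(ids, metadata$sample_id), ]
  keep <- !is.na(md[[factor]])
  if (sum(keep) < 3) stop("fewer than 3 samples with non-missing factor")
  dm <- as.matrix(dist)[keep, keep]
  x <- md[[factor]][keep]
  n <- sum(keep)
  if (is.character(x) || is.factor(x) || is.logical(x)) {
    x <- droplevels(as.factor(x))
    if (nlevels(x) < 2) {
      stop(sprintf("factor '%s' has a single level '%s'", factor,
                   levels(x)[1]), call. = FALSE)
    }
    small <- table(x)
    if (any(small < 2)) {
      stop(sprintf("level '%s' of factor '%s' has fewer than 2 samples",
                   names(small)[small < 2][1], factor), call. = FALSE)
    }
    X <- model.matrix(~x)
  } else {
    X <- cbind(1, as.numeric(x))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design for factor ", factor)
  H <- tcrossprod(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE])
  Cn <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * Cn %*% dm^2 %*% Cn
  df1 <- qrX$rank - 1
  df2 <- n - qrX$rank
  res <- permanova_perm_cpp(G, H, df1, df2, as.integer(n_permutations),
                            as.integer(seed))
  tibble::tibble(factor = factor,
                 r_squared = res$r_squared,
                 f_statistic = res$f_obs,
                 p_value = (1 + res$count_ge) / (1 + n_permutations),
                 n_permutations = as.integer(n_permutations),
                 n_samples = n)
}

#' Screen metadata factors by marginal PERMANOVA
#'
#' Runs one marginal PERMANOVA per factor on the samples non-missing for
#' that factor, then adjusts p-values by Benjamini-Hochberg across the
#' factors tested. Results are ordered by variance explained.
#'
#' Factors that cannot be tested in the cohort at hand (a single level, a
#' level with fewer than 2 samples, too much missingness) are skipped with
#' a warning; the BH family is the set of factors actually tested.
#'
#' @inheritParams permanova
#' @param factors Character vector of metadata columns (at least one).
#' @return Tibble of per-factor results with a `q_value` column, ordered by
#'   `r_squared` descending.
#' @export
factor_screen <- function(dist, metadata, factors, n_permutations = 1000,
                          seed = 1L) {
  if (length(factors) < 1) stop("at least one factor is required")
  res <- purrr::map(factors, function(f) {
    tryCatch(
      permanova(dist, metadata, f, n_permutations = n_permutations,
                seed = derive_seed(seed, f)),
      error = function(e) {
        warning(sprintf("skipping factor '%s': %s", f,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
  })
  res <- dplyr::bind_rows(res)
  if (nrow(res) == 0) stop("no testable factor in the screen", call. = FALSE)
  res |>
    dplyr::mutate(q_value = bh_fdr(.data$p_value)) |>
    dplyr::arrange(dplyr::desc(.data$r_squared))
}

#' Spearman rank correlation with two-sided p-value
#'
#' Midrank-tied Spearman correlation; p-values use exact permutation
#' enumeration for n <= 9 without ties and the t approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble: `estimate`, `p_value`, `n`, `degenerate` (TRUE
#'   when a side has zero rank variance, in which case `estimate` is NA).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) {
    warning("zero rank variance; Spearman correlation undefined")
    return(tibble::tibble(estimate = NA_real_, p_value = NA_real_, n = n,
                          degenerate = TRUE))
  }
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = (n <= 9 && !has_ties)))
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 n = n, degenerate = FALSE)
}

#' Within-group dispersion comparison of beta diversity
#'
#' Group "beta diversity" comparison implemented as distance-to-centroid
#' dispersion (via [vegan::betadisper()]) compared between two groups by a
#' Wilcoxon rank-sum test.
#'
#' @inheritParams permanova
#' @param group Name of a two-level metadata column.
#' @return List with `dispersion` (tibble: sample_id, group, dist_to_centroid)
#'   and `p_value`.
#' @export
beta_dispersion <- function(dist, metadata, group = "group") {
  ids <- attr(dist, "Labels")
  g <- metadata[[group]][match(ids, metadata$sample_id)]
  if (length(unique(g)) != 2) stop("group must have exactly 2 levels")
  bd <- vegan::betadisper(dist, g)
  d <- as.numeric(bd$distances)
  w <- wilcoxon_rank_sum(d[g == unique(g)[1]], d[g == unique(g)[2]])
  list(dispersion = tibble::tibble(sample_id = ids, group = g,
                                   dist_to_centroid = d),
       p_value = w$p_value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
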