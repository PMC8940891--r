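# Internal helpers shared across modules.

# Convert a feature tibble (first column sample_id, remaining numeric feature
# columns) to a numeric matrix with sample ids as rownames.
ft_matrix <- function(data, arg = "data") {
  if (!is.data.frame(data)) {
    stop(sprintf("`%s` must be a data frame with a sample_id column", arg),
         call. = FALSE)
  }
  if (!"sample_id" %in% names(data)) {
    stop(sprintf("`%s` must have a 'sample_id' first column", arg),
         call. = FALSE)
  }
  ids <- as.character(data$sample_id)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("duplicated sample_id '%s' in `%s`", dup, arg), call. = FALSE)
  }
  vals <- data[setdiff(names(data), "sample_id")]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    bad <- names(vals)[!vapply(vals, is.numeric, logical(1))][1]
    stop(sprintf("feature column '%s' is not numeric", bad), call. = FALSE)
  }
  if (anyDuplicated(names(vals))) {
    dup <- names(vals)[duplicated(names(vals))][1]
    stop(sprintf("duplicated feature id '%s'", dup), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

# Inverse of ft_matrix().
ft_tibble <- function(m) {
  tibble::as_tibble(as.data.frame(m), .name_repair = "minimal") |>
    dplyr::mutate(sample_id = rownames(m), .before = 1)
}

check_nonnegative <- function(m, arg = "data") {
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value in `%s` at sample '%s', feature '%s'", arg,
                 rownames(m)[idx[1]], colnames(m)[idx[2]]), call. = FALSE)
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value in `%s` at sample '%s', feature '%s'", arg,
                 rownames(m)[idx[1]], colnames(m)[idx[2]]), call. = FALSE)
  }
  invisible(m)
}

# Deterministic per-stage seed derived from a global seed; stays within the
# 32-bit integer range R requires.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

# Spearman correlation of the columns of x against the columns of y with
# two-sided p-values from the t approximation (the regime used for the
# n > 9 sample sizes of association scans).
spearman_matrix <- function(x, y) {
  n <- nrow(x)
  r <- suppressWarnings(cor(x, y, method = "spearman"))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  list(r = r, p = p)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster assignments of the same
#' items; 1 for identical partitions, approximately 0 for independent ones.
#' Used to score recovery of planted covariation clusters.
#'
#' @param a,b Vectors of cluster labels (any type coercible to factor),
#'   aligned element-wise.
#' @return A single number in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
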