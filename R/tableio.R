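#' Read a samples-by-features abundance or intensity table
#'
#' Reads a TSV feature table in the conventions of MetaPhlAn-style taxonomic
#' profiles and untargeted LC-MS feature matrices: a header row of ids and a
#' first column of ids. Orientation is auto-detected from the header token
#' `sample_id`; transposed files (features in rows) are transposed on read.
#'
#' @param path Path to a tab-separated file (UTF-8, `.` decimal separator).
#' @param kind Either `"intensity"` (metabolite feature matrix) or
#'   `"relative_abundance"` (compositional taxon profile; each row must sum
#'   to at most 1 + 1e-6).
#' @param orientation `"auto"` (default, keyed on the `sample_id` header
#'   token), `"samples_in_rows"` or `"features_in_rows"`.
#' @return A tibble with a `sample_id` column followed by one numeric column
#'   per feature.
#' @export
read_feature_table <- function(path, kind = c("intensity", "relative_abundance"),
                               orientation = c("auto", "samples_in_rows",
                                               "features_in_rows")) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", dec = ".",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("feature table needs an id column plus at least one value column")
  first <- names(raw)[1]
  if (orientation == "auto") {
    orientation <- if (identical(first, "sample_id")) "samples_in_rows"
                   else "features_in_rows"
  }
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[-1])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("non-numeric value at row %d ('%s'), column '%s' of %s",
                   bad[1, 1], ids[bad[1, 1]], colnames(m)[bad[1, 2]], path))
    }
    m <- matrix(as.numeric(m), nrow(m), dimnames = dimnames(m))
  }
  rownames(m) <- ids
  if (orientation == "features_in_rows") m <- t(m)
  out <- ft_tibble(m)
  validate_feature_table(out, kind = kind)
  out
}

#' Write a feature table as TSV
#'
#' @param data Feature tibble (`sample_id` + numeric feature columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  ft_matrix(data)  # validates shape
  readr::write_tsv(data, path)
  invisible(path)
}

#' Validate a feature table against its kind invariants
#'
#' Checks for duplicated ids, non-numeric or negative entries, and (for
#' relative abundances) row sums not exceeding 1 + 1e-6. Errors name the
#' offending sample/feature cell.
#'
#' @inheritParams read_feature_table
#' @param data Feature tibble.
#' @return `data`, invisibly.
#' @export
validate_feature_table <- function(data, kind = c("intensity", "relative_abundance")) {
  kind <- match.arg(kind)
  m <- ft_matrix(data)
  check_nonnegative(m)
  if (kind == "relative_abundance") {
    rs <- rowSums(m)
    if (any(rs > 1 + 1e-6)) {
      bad <- rownames(m)[which.max(rs)]
      stop(sprintf("sample '%s' has relative abundances summing to %.6f > 1",
                   bad, max(rs)), call. = FALSE)
    }
  }
  invisible(data)
}

#' Read per-sample metadata
#'
#' Expects a TSV with a `sample_id` column plus clinical/questionnaire
#' columns; missing values are encoded as `NA`. Group and depression-class
#' columns are kept as character.
#'
#' @param path Path to a tab-separated metadata file.
#' @return A tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(md)) stop("metadata needs a 'sample_id' column")
  if (anyDuplicated(md$sample_id)) {
    stop(sprintf("duplicated sample_id '%s' in metadata",
                 md$sample_id[duplicated(md$sample_id)][1]))
  }
  md
}

#' Prevalence filter for species relative abundances
#'
#' Keeps species whose relative abundance strictly exceeds `min_abund` in at
#' least `min_samples` samples (defaults: 0.1% in at least 6 samples, the
#' standard desk filter for shotgun species profiles). The sample axis is
#' unchanged; rows are not renormalized.
#'
#' @param data Relative-abundance feature tibble.
#' @param min_abund Strict abundance threshold (proportion).
#' @param min_samples Minimum number of samples exceeding the threshold.
#' @return The filtered feature tibble.
#' @export
filter_species <- function(data, min_abund = 0.001, min_samples = 6) {
  validate_feature_table(data, kind = "relative_abundance")
  m <- ft_matrix(data)
  keep <- colSums(m > min_abund) >= min_samples
  ft_tibble(m[, keep, drop = FALSE])
}

#' Total-sum scaling to relative abundances
#'
#' Divides each sample's values by its total so rows sum to 1. Idempotent on
#' already-normalized tables; preserves within-sample rank order.
#'
#' @param data Feature tibble with at least one positive value per sample.
#' @return A relative-abundance feature tibble.
#' @export
total_sum_scale <- function(data) {
  m <- ft_matrix(data)
  check_nonnegative(m)
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    stop(sprintf("sample '%s' has no positive values; cannot normalize",
                 rownames(m)[which(rs <= 0)[1]]), call. = FALSE)
  }
  ft_tibble(m / rs)
}
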