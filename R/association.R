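#' Species-metabolite association scan in cases
#'
#' Spearman correlation of every (species, metabolite) pair across the case
#' samples, with BH q-values over the full pair family actually tested.
#' Pairs involving a feature constant within cases are skipped (rank
#' correlation undefined) and logged via a message; skipped pairs are
#' excluded from the BH family.
#'
#' @param species_data,metabolite_data Feature tibbles sharing the sample
#'   axis.
#' @param case_samples Character vector of case sample ids.
#' @param species_set,metabolite_set Feature ids to scan (default: all
#'   columns); typically the differentially abundant sets.
#' @param q_cutoff Discovery FDR cutoff (default 0.05).
#' @return A tibble of class `assoc_records`: `species_id`, `metabolite_id`,
#'   `r_case`, `p_case`, `q_case`, `discovered`.
#' @export
associate <- function(species_data, metabolite_data, case_samples,
                      species_set = NULL, metabolite_set = NULL,
                      q_cutoff = 0.05) {
  sm <- ft_matrix(species_data, "species_data")
  mm <- ft_matrix(metabolite_data, "metabolite_data")
  if (is.null(species_set)) species_set <- colnames(sm)
  if (is.null(metabolite_set)) metabolite_set <- colnames(mm)
  if (length(species_set) == 0 || length(metabolite_set) == 0) {
    stop("species_set and metabolite_set must be nonempty", call. = FALSE)
  }
  stopifnot(all(species_set %in% colnames(sm)),
            all(metabolite_set %in% colnames(mm)),
            all(case_samples %in% rownames(sm)),
            all(case_samples %in% rownames(mm)))
  xs <- sm[case_samples, species_set, drop = FALSE]
  ys <- mm[case_samples, metabolite_set, drop = FALSE]
  const_s <- apply(xs, 2, function(v) sd(v) == 0)
  const_m <- apply(ys, 2, function(v) sd(v) == 0)
  if (any(const_s) || any(const_m)) {
    message(sprintf("skipping %d constant species and %d constant metabolites in cases",
                    sum(const_s), sum(const_m)))
  }
  xs <- xs[, !const_s, drop = FALSE]
  ys <- ys[, !const_m, drop = FALSE]
  sp <- spearman_matrix(xs, ys)
  res <- tidyr::expand_grid(species_id = colnames(xs),
                            metabolite_id = colnames(ys))
  idx <- cbind(match(res$species_id, colnames(xs)),
               match(res$metabolite_id, colnames(ys)))
  res <- res |>
    dplyr::mutate(
      r_case = sp$r[idx],
      p_case = sp$p[idx],
      q_case = bh_fdr(.data$p_case),
      discovered = .data$q_case < q_cutoff)
  class(res) <- c("assoc_records", class(res))
  attr(res, "q_cutoff") <- q_cutoff
  attr(res, "case_samples") <- case_samples
  res
}

#' Replication filter on control samples
#'
#' Recomputes each discovered association on the control samples and flags
#' it replicated when it is nominally significant there (`p < p_cutoff`)
#' with the same correlation sign. The replicated set is always a subset of
#' the discovered set.
#'
#' @param records An `assoc_records` tibble from [associate()].
#' @param species_data,metabolite_data Feature tibbles (same as discovery).
#' @param control_samples Character vector of control sample ids (>= 5,
#'   disjoint from the case samples).
#' @param p_cutoff Nominal replication cutoff (default 0.05).
#' @return `records` with added `r_control`, `p_control`, `same_direction`,
#'   `replicated`.
#' @export
replicate_associations <- function(records, species_data, metabolite_data,
                                   control_samples, p_cutoff = 0.05) {
  stopifnot(inherits(records, "assoc_records"))
  if (length(control_samples) < 5) {
    stop("need at least 5 control samples for replication", call. = FALSE)
  }
  if (length(intersect(control_samples, attr(records, "case_samples"))) > 0) {
    stop("control samples must be disjoint from the discovery case samples",
         call. = FALSE)
  }
  sm <- ft_matrix(species_data, "species_data")
  mm <- ft_matrix(metabolite_data, "metabolite_data")
  xs <- sm[control_samples, unique(records$species_id), drop = FALSE]
  ys <- mm[control_samples, unique(records$metabolite_id), drop = FALSE]
  sp <- spearman_matrix(xs, ys)
  idx <- cbind(match(records$species_id, colnames(xs)),
               match(records$metabolite_id, colnames(ys)))
  out <- records |>
    dplyr::mutate(
      r_control = sp$r[idx],
      p_control = sp$p[idx],
      same_direction = sign(.data$r_case) == sign(.data$r_control) &
        sign(.data$r_case) != 0,
      replicated = .data$discovered & .data$p_control < p_cutoff &
        .data$same_direction)
  out$same_direction[is.na(out$same_direction)] <- FALSE
  out$replicated[is.na(out$replicated)] <- FALSE
  out
}

#' Wide association matrix for plotting
#'
#' Reshapes association records into a dense species-by-metabolite matrix
#' of discovery correlations plus a logical mask of discovered (q below
#' cutoff) pairs. Untested pairs are `NaN`.
#'
#' @param records An `assoc_records` tibble.
#' @return List of class `assoc_matrix` with `r` and `mask` matrices.
#' @export
association_heatmap_data <- function(records) {
  stopifnot(inherits(records, "assoc_records"))
  sp <- unique(records$species_id)
  met <- unique(records$metabolite_id)
  r <- matrix(NaN, length(sp), length(met), dimnames = list(sp, met))
  mask <- matrix(FALSE, length(sp), length(met), dimnames = list(sp, met))
  idx <- cbind(match(records$species_id, sp),
               match(records$metabolite_id, met))
  r[idx] <- records$r_case
  mask[idx] <- records$discovered
  structure(list(r = r, mask = mask), class = "assoc_matrix")
}
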