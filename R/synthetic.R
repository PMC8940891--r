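#' Configuration for a synthetic multi-omics cohort
#'
#' Captures the generative conditions of an IBS-style case-control cohort:
#' a compositional species table with log-normal loads and detection-limit
#' sparsity, zero-inflated log-normal fecal/serum metabolite intensities,
#' planted case/control effects, planted covarying metabolite clusters and
#' planted species-metabolite monotone couplings, plus clinical covariates
#' (age, HAMD, SDS) consistent with depression strata.
#'
#' Defaults mirror the discovery-cohort geometry of a large IBS-D study
#' (214 cases, 66 controls) at desk-scale feature counts.
#'
#' @param n_case,n_control Number of case (IBS) and control (HC) samples.
#' @param n_species,n_metabolites Number of microbial species and of
#'   metabolite features per metabolome table.
#' @param frac_differential Fraction of features (per table) given a planted
#'   case/control effect.
#' @param log_fold_effect Log-scale group-mean shift for planted
#'   differential features (default `log(2)`).
#' @param cluster_sizes Integer sizes of planted covariation clusters among
#'   differential fecal metabolites (may be empty).
#' @param cluster_corr Target intra-cluster pairwise Spearman correlation,
#'   in (0, 1).
#' @param n_associations Number of planted species-metabolite couplings.
#' @param assoc_strength Target absolute Spearman correlation of planted
#'   couplings within cases, in (0, 1).
#' @param assoc_in_controls If `TRUE` (default) planted couplings hold in
#'   controls as well, so they survive the replication filter; if `FALSE`
#'   they exist in cases only.
#' @param zero_inflation Per-feature zero fraction of metabolite tables, in
#'   \[0, 1\). Zeros arise by detection-limit censoring of the lowest
#'   intensities, the mechanism that produces missing peaks in untargeted
#'   LC-MS and that keeps rank correlations of co-varying features intact.
#' @param age_range Two-element numeric range of ages in years.
#' @param seed Integer seed; a fixed config (including seed) reproduces the
#'   cohort exactly.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_case = 214, n_control = 66,
                         n_species = 150, n_metabolites = 400,
                         frac_differential = 0.15,
                         log_fold_effect = log(2),
                         cluster_sizes = c(15L, 10L, 5L),
                         cluster_corr = 0.8,
                         n_associations = 20,
                         assoc_strength = 0.6,
                         assoc_in_controls = TRUE,
                         zero_inflation = 0.2,
                         age_range = c(18, 65),
                         seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_species = as.integer(n_species),
              n_metabolites = as.integer(n_metabolites),
              frac_differential = frac_differential,
              log_fold_effect = log_fold_effect,
              cluster_sizes = as.integer(cluster_sizes),
              cluster_corr = cluster_corr,
              n_associations = as.integer(n_associations),
              assoc_strength = assoc_strength,
              assoc_in_controls = isTRUE(assoc_in_controls),
              zero_inflation = zero_inflation,
              age_range = as.numeric(age_range), seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid synth_config: ", msg, call. = FALSE)
  chk(cfg$n_case >= 3 && cfg$n_control >= 3,
      "n_case and n_control must each be at least 3")
  chk(cfg$n_species >= 1 && cfg$n_metabolites >= 1,
      "n_species and n_metabolites must be positive")
  chk(cfg$frac_differential >= 0 && cfg$frac_differential <= 1,
      "frac_differential must be in [0, 1]")
  chk(cfg$zero_inflation >= 0 && cfg$zero_inflation < 1,
      "zero_inflation must be in [0, 1)")
  chk(all(cfg$cluster_sizes >= 2) || length(cfg$cluster_sizes) == 0,
      "cluster_sizes must each be at least 2")
  n_diff <- round(cfg$frac_differential * cfg$n_metabolites)
  chk(sum(cfg$cluster_sizes) <= n_diff,
      sprintf("sum(cluster_sizes) = %d exceeds the %d differential metabolites implied by frac_differential",
              sum(cfg$cluster_sizes), n_diff))
  chk(cfg$n_associations <= max(n_diff - sum(cfg$cluster_sizes), 0),
      sprintf("n_associations = %d exceeds the %d differential metabolites left after cluster planting",
              cfg$n_associations, max(n_diff - sum(cfg$cluster_sizes), 0)))
  chk(length(cfg$cluster_sizes) == 0 ||
        (cfg$cluster_corr > 0 && cfg$cluster_corr < 1),
      "cluster_corr must be in (0, 1)")
  chk(cfg$n_associations == 0 ||
        (cfg$assoc_strength > 0 && cfg$assoc_strength < 1),
      "assoc_strength must be in (0, 1)")
  chk(length(cfg$age_range) == 2 && cfg$age_range[1] < cfg$age_range[2],
      "age_range must be (min, max) with min < max")
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed must be an integer")
  invisible(cfg)
}

#' Depression stratum from HAMD and SDS scores
#'
#' IBS samples are stratified by an SDS screen (self-rating cutoff 53)
#' followed by clinician HAMD severity: no depression (`rIBS`) when
#' HAMD <= 7 or the SDS screen is negative, mild (`mIBS`) for HAMD 8-16
#' with SDS > 53, moderate-to-severe (`sIBS`) for HAMD >= 17 with SDS > 53.
#' HAMD exactly 7 falls between the published strata bounds and is resolved
#' to `rIBS`.
#'
#' @param hamd,sds Non-negative numeric score vectors (recycled to common
#'   length).
#' @return Character vector of `"rIBS"`, `"mIBS"`, `"sIBS"`.
#' @export
#' @examples
#' stratify_depression(c(5, 10, 20), c(40, 60, 60))
stratify_depression <- function(hamd, sds) {
  if (any(hamd < 0, na.rm = TRUE) || any(sds < 0, na.rm = TRUE)) {
    stop("hamd and sds scores must be non-negative", call. = FALSE)
  }
  n <- max(length(hamd), length(sds))
  hamd <- rep_len(hamd, n); sds <- rep_len(sds, n)
  out <- rep("rIBS", n)
  out[sds > 53 & hamd >= 8 & hamd <= 16] <- "mIBS"
  out[sds > 53 & hamd >= 17] <- "sIBS"
  out[is.na(hamd) | is.na(sds)] <- NA_character_
  out
}

# Censor the lowest `frac` fraction of a vector to zero (per-feature
# detection limit). Rank-based so the zero fraction is exact up to rounding.
censor_low <- function(x, frac) {
  if (frac <= 0) return(x)
  k <- floor(frac * length(x))
  if (k >= 1) x[rank(x, ties.method = "first") <= k] <- 0
  x
}

# Generic monotone bisection used by the loading calibrations: find rho in
# (0, 1) with realized(rho) = target, where realized() is evaluated on one
# fixed noise draw so it is monotone in rho.
bisect_loading <- function(realized, target) {
  lo <- 0; hi <- 0.9999
  if (realized(hi) <= target) return(hi)
  for (i in 1:18) {
    mid <- (lo + hi) / 2
    if (realized(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Calibrate the shared-factor variance fraction rho so that two cluster
# members (each loading sqrt(rho) on the factor), after detection-limit
# censoring of both at rate zi, show pairwise Spearman correlation `target`.
# shift_z is the coherent case-group shift in z units (log effect / sigma)
# and case_frac the case fraction; the shift itself correlates members, so
# calibrating with it avoids overshooting the target.
calibrate_cluster_loading <- function(target, zi, shift_z = 0,
                                      case_frac = 0.5, n = 2000) {
  f <- rnorm(n); e1 <- rnorm(n); e2 <- rnorm(n)
  case <- as.numeric(seq_len(n) <= round(case_frac * n))
  realized <- function(rho) {
    x <- censor_low(exp(sqrt(rho) * f + sqrt(1 - rho) * e1 + shift_z * case), zi)
    y <- censor_low(exp(sqrt(rho) * f + sqrt(1 - rho) * e2 + shift_z * case), zi)
    suppressWarnings(cor(x, y, method = "spearman"))
  }
  bisect_loading(realized, target)
}

# Calibrate the loading of a coupled metabolite on the normal scores g of an
# observed species abundance vector so that, within the `subset` samples and
# after censoring the metabolite at rate zi, |Spearman| hits `target`.
calibrate_assoc_loading <- function(target, species_values, g, subset, zi) {
  e <- rnorm(length(g))
  realized <- function(rho) {
    y <- censor_low(exp(0.5 * (sqrt(rho) * g + sqrt(1 - rho) * e)), zi)
    suppressWarnings(cor(species_values[subset], y[subset],
                         method = "spearman"))
  }
  bisect_loading(realized, target)
}

#' Generate a synthetic discovery/validation cohort with ground truth
#'
#' Draws a full multi-omics bundle under a [synth_config()]: a compositional
#' species relative-abundance table, fecal and serum metabolite intensity
#' tables, per-sample metadata, and the planted ground truth (differential
#' feature ids with direction, cluster membership, species-metabolite
#' couplings with sign).
#'
#' Mechanics: species loads and metabolite intensities are log-normal;
#' planted differentials receive a case-group log shift of
#' `log_fold_effect` with random direction; cluster members share a
#' per-cluster standard-normal latent factor whose loading is calibrated
#' numerically so censored pairwise Spearman correlation matches
#' `cluster_corr`; coupled metabolites load on the standardized log-load of
#' their partner species, calibrated to `assoc_strength`; zeros arise by
#' per-feature detection-limit censoring at rate `zero_inflation` (species
#' sparsity uses per-species censoring fractions drawn up to 50%). Species
#' rows are renormalized to sum to one after censoring.
#'
#' @param config A [synth_config()].
#' @param noise_seed Optional integer. The planted "world" (which features
#'   are differential and in which direction, cluster membership, coupling
#'   pairs and signs, feature-level baselines) is always drawn from
#'   `config$seed`; the sampling noise (subjects, metadata, measurement
#'   draws) is drawn from `noise_seed` when given. Two calls with the same
#'   config but different `noise_seed` values therefore emulate discovery
#'   and validation cohorts from one generative process.
#' @return A list of class `momics_cohort` with elements `microbiome`,
#'   `fecal_mets`, `serum_mets` (feature tibbles), `metadata` (tibble) and
#'   `truth` (list with `differential_ids`, `cluster_membership`,
#'   `association_pairs`, `seed`).
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(n_case = 30, n_control = 20,
#'   n_species = 40, n_metabolites = 60, cluster_sizes = c(4L),
#'   n_associations = 3, seed = 7))
#' dim(cohort$microbiome)
generate_cohort <- function(config, noise_seed = NULL) {
  validate_synth_config(config)
  cfg <- config
  n <- cfg$n_case + cfg$n_control
  sample_ids <- sprintf("S%04d", seq_len(n))
  is_case <- c(rep(TRUE, cfg$n_case), rep(FALSE, cfg$n_control))
  species_ids <- sprintf("sp%04d", seq_len(cfg$n_species))
  fecal_ids <- sprintf("fm%04d", seq_len(cfg$n_metabolites))
  serum_ids <- sprintf("sm%04d", seq_len(cfg$n_metabolites))

  ## ---- world phase: planted structure and feature-level parameters -----
  set.seed(cfg$seed)
  n_diff_sp <- round(cfg$frac_differential * cfg$n_species)
  diff_sp <- sort(sample(species_ids, n_diff_sp))
  dir_sp <- setNames(sample(c(-1, 1), n_diff_sp, replace = TRUE), diff_sp)
  mu_sp <- rnorm(cfg$n_species, 0, 2)
  zi_sp <- setNames(runif(cfg$n_species, 0, 0.5), species_ids)

  n_diff <- round(cfg$frac_differential * cfg$n_metabolites)
  diff_fm <- sort(sample(fecal_ids, n_diff))
  dir_fm <- setNames(sample(c(-1, 1), n_diff, replace = TRUE), diff_fm)
  cluster_members <- list()
  pool <- diff_fm
  if (length(cfg$cluster_sizes) > 0) {
    picked <- sample(pool, sum(cfg$cluster_sizes))
    cluster_members <- split(picked, rep(seq_along(cfg$cluster_sizes),
                                         cfg$cluster_sizes))
    pool <- setdiff(pool, picked)
    # covariation clusters shift coherently: one enrichment direction per
    # cluster, otherwise opposing group shifts break the planted correlation
    for (members in cluster_members) {
      dir_fm[members] <- sample(c(-1, 1), 1)
    }
  }
  assoc_pairs <- NULL
  if (cfg$n_associations > 0) {
    assoc_mets <- sample(pool, cfg$n_associations)
    assoc_sp <- rep_len(if (n_diff_sp > 0) diff_sp else species_ids,
                        cfg$n_associations)
    assoc_sign <- sample(c(-1, 1), cfg$n_associations, replace = TRUE)
    assoc_pairs <- tibble::tibble(species_id = assoc_sp,
                                  metabolite_id = assoc_mets,
                                  sign = assoc_sign)
  }
  diff_sm <- sort(sample(serum_ids, n_diff))
  dir_sm <- setNames(sample(c(-1, 1), n_diff, replace = TRUE), diff_sm)
  mu_fm <- setNames(runif(cfg$n_metabolites, log(10), log(1000)), fecal_ids)
  mu_sm <- setNames(runif(cfg$n_metabolites, log(10), log(1000)), serum_ids)

  ## ---- noise phase: subjects and measurements --------------------------
  set.seed(if (is.null(noise_seed)) cfg$seed else
             derive_seed(noise_seed, "noise"))
  metadata <- simulate_metadata(sample_ids, is_case, cfg)

  z_sp <- matrix(rnorm(n * cfg$n_species), n, cfg$n_species,
                 dimnames = list(sample_ids, species_ids))
  log_load <- sweep(z_sp, 2, mu_sp, function(z, m) m + 1.0 * z)
  for (s in diff_sp) {
    log_load[is_case, s] <- log_load[is_case, s] + dir_sp[s] * cfg$log_fold_effect
  }
  loads <- exp(log_load)
  for (j in seq_len(ncol(loads))) loads[, j] <- censor_low(loads[, j], zi_sp[j])
  rs <- rowSums(loads)
  if (any(rs <= 0)) stop("a sample lost all species to censoring; lower zero fractions")
  microbiome <- ft_tibble(loads / rs)

  species_mat <- ft_matrix(microbiome)
  fecal <- simulate_metabolome(fecal_ids, mu_fm, diff_fm, dir_fm,
                               cluster_members, assoc_pairs, species_mat,
                               is_case, cfg, sample_ids)
  serum <- simulate_metabolome(serum_ids, mu_sm, diff_sm, dir_sm, list(),
                               NULL, species_mat, is_case, cfg, sample_ids)

  dir_label <- function(d) {
    out <- rep("control_enriched", length(d))
    out[d > 0] <- "case_enriched"
    out
  }
  truth <- list(
    differential_ids = dplyr::bind_rows(
      tibble::tibble(feature_id = diff_sp, table = "species",
                     direction = dir_label(dir_sp)),
      tibble::tibble(feature_id = diff_fm, table = "fecal",
                     direction = dir_label(dir_fm)),
      tibble::tibble(feature_id = diff_sm, table = "serum",
                     direction = dir_label(dir_sm))),
    cluster_membership = if (length(cluster_members) > 0) {
      tibble::tibble(
        feature_id = unlist(cluster_members, use.names = FALSE),
        cluster = rep(seq_along(cluster_members),
                      lengths(cluster_members)))
    } else {
      tibble::tibble(feature_id = character(), cluster = integer())
    },
    association_pairs = if (is.null(assoc_pairs)) {
      tibble::tibble(species_id = character(), metabolite_id = character(),
                     sign = integer())
    } else assoc_pairs,
    seed = cfg$seed)

  structure(list(microbiome = microbiome, fecal_mets = fecal,
                 serum_mets = serum, metadata = metadata, truth = truth,
                 config = cfg),
            class = "momics_cohort")
}

# Clinical covariates consistent with the depression strata: an SDS screen
# at 53 then HAMD severity bands. Subtype and stratum frequencies mirror a
# 264-patient discovery cohort (24 IBS-C / 214 IBS-D / 19 IBS-M / 7 IBS-U;
# 185 rIBS / 63 mIBS / 16 sIBS).
simulate_metadata <- function(sample_ids, is_case, cfg) {
  n <- length(sample_ids)
  n_case <- sum(is_case)
  subtype <- rep("none", n)
  subtype[is_case] <- sample(c("IBS-C", "IBS-D", "IBS-M", "IBS-U"), n_case,
                             replace = TRUE,
                             prob = c(24, 214, 19, 7) / 264)
  depr <- rep("HC", n)
  depr[is_case] <- sample(c("rIBS", "mIBS", "sIBS"), n_case, replace = TRUE,
                          prob = c(185, 63, 16) / 264)
  hamd <- integer(n); sds <- integer(n)
  for (i in seq_len(n)) {
    switch(depr[i],
      HC   = { hamd[i] <- sample(0:5, 1);   sds[i] <- sample(20:45, 1) },
      rIBS = { hamd[i] <- sample(0:7, 1);   sds[i] <- sample(25:53, 1) },
      mIBS = { hamd[i] <- sample(8:16, 1);  sds[i] <- sample(54:70, 1) },
      sIBS = { hamd[i] <- sample(17:30, 1); sds[i] <- sample(54:75, 1) })
  }
  stopifnot(all(stratify_depression(hamd[is_case], sds[is_case]) ==
                  depr[is_case]))
  tibble::tibble(
    sample_id = sample_ids,
    group = ifelse(is_case, "IBS", "HC"),
    subtype = subtype,
    age = round(runif(n, cfg$age_range[1], cfg$age_range[2])),
    bmi = round(rnorm(n, 22, 2.5), 1),
    hamd = hamd, sds = sds,
    depression_class = depr)
}

simulate_metabolome <- function(feature_ids, mu, diff_ids, dir,
                                cluster_members, assoc_pairs, species_mat,
                                is_case, cfg, sample_ids) {
  n <- length(sample_ids)
  p <- length(feature_ids)
  sigma <- 0.5
  z <- matrix(rnorm(n * p), n, p, dimnames = list(sample_ids, feature_ids))

  if (length(cluster_members) > 0) {
    # the factor alone is scaled to cluster_corr; the coherent group shift
    # of differential members adds a little on top of this on the raw scale
    # and is removed again by residualization downstream
    rho_c <- calibrate_cluster_loading(cfg$cluster_corr, cfg$zero_inflation)
    for (members in cluster_members) {
      f <- rnorm(n)
      z[, members] <- sqrt(rho_c) * f +
        sqrt(1 - rho_c) * z[, members, drop = FALSE]
    }
  }
  if (!is.null(assoc_pairs) && nrow(assoc_pairs) > 0) {
    for (k in seq_len(nrow(assoc_pairs))) {
      s <- assoc_pairs$species_id[k]
      m <- assoc_pairs$metabolite_id[k]
      sp_val <- species_mat[, s]
      # couple on the normal scores of the observed (censored, renormalized)
      # relative abundances so rank coupling survives compositional effects
      g <- as.numeric(scale(
        qnorm(rank(sp_val, ties.method = "average") / (n + 1))))
      rho_a <- calibrate_assoc_loading(cfg$assoc_strength, sp_val, g,
                                       which(is_case), cfg$zero_inflation)
      z[, m] <- assoc_pairs$sign[k] * sqrt(rho_a) * g +
        sqrt(1 - rho_a) * z[, m]
      if (!cfg$assoc_in_controls) {
        z[!is_case, m] <- rnorm(sum(!is_case))
      }
    }
  }

  logx <- sweep(z * sigma, 2, mu, `+`)
  for (s in diff_ids) {
    logx[is_case, s] <- logx[is_case, s] + dir[s] * cfg$log_fold_effect
  }
  x <- exp(logx)
  for (j in seq_len(p)) x[, j] <- censor_low(x[, j], cfg$zero_inflation)
  ft_tibble(x)
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes the three feature tables and metadata as TSV and the ground truth
#' as JSON under `dir`.
#'
#' @param cohort A `momics_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "momics_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(cohort$microbiome, file.path(dir, "microbiome.tsv"))
  write_feature_table(cohort$fecal_mets, file.path(dir, "fecal_metabolites.tsv"))
  write_feature_table(cohort$serum_mets, file.path(dir, "serum_metabolites.tsv"))
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
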