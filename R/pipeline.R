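#' Pipeline configuration
#'
#' Bundles every stage parameter with defaults matching the published
#' thresholds this workflow standardizes on: species prevalence filter
#' 0.1% in >= 6 samples; Wilcoxon + BH differential criteria (FDR < 0.05
#' univariate; VIP > 1.0, FDR < 0.1, fold-change band 0.8-1.2 combined);
#' covariation clustering at Spearman r = 0.7 on residual abundances;
#' association discovery q < 0.05 with replication p < 0.05; PERMANOVA with
#' 1000 permutations; random forest with 500 trees, 5 trials of 10-fold
#' cross-validation.
#'
#' @param simulate A [synth_config()] describing the cohort to simulate, or
#'   `NULL` when reading `input_dir`.
#' @param input_dir Directory holding `microbiome.tsv`,
#'   `fecal_metabolites.tsv`, `serum_metabolites.tsv`, `metadata.tsv` (as
#'   written by [write_cohort()]); ignored when `simulate` is given.
#' @param stages Character subset of
#'   `c("diversity", "differential", "cluster", "associate", "classify")`.
#' @param species_min_abund,species_min_samples Prevalence filter.
#' @param criteria A [criteria_config()] for metabolite differential calls.
#' @param screen_factors Metadata columns for the PERMANOVA factor screen.
#' @param n_permutations PERMANOVA permutations.
#' @param r_threshold Covariation-cluster similarity threshold.
#' @param assoc_q_cutoff,assoc_p_cutoff Association discovery/replication
#'   cutoffs.
#' @param rf List of forest settings: `ntree`, `n_trials`, `n_folds`,
#'   `counts` (NULL for the default grid), `n_boot`.
#' @param seed Global seed; per-stage seeds are derived deterministically
#'   from it.
#' @param outdir Output directory for stage artifacts and the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = synth_config(), input_dir = NULL,
                            stages = c("diversity", "differential",
                                       "cluster", "associate", "classify"),
                            species_min_abund = 0.001,
                            species_min_samples = 6,
                            criteria = criteria_config(),
                            screen_factors = c("group", "subtype", "age",
                                               "bmi", "hamd", "sds",
                                               "depression_class"),
                            n_permutations = 1000,
                            r_threshold = 0.7,
                            assoc_q_cutoff = 0.05, assoc_p_cutoff = 0.05,
                            rf = list(ntree = 500, n_trials = 5,
                                      n_folds = 10, counts = NULL,
                                      n_boot = 2000),
                            seed = 1L, outdir = tempfile("momics_run_")) {
  stages <- if (length(stages) == 0) character(0)
            else match.arg(stages, several.ok = TRUE)
  if (is.null(simulate) && is.null(input_dir)) {
    stop("either a simulate block or an input_dir is required", call. = FALSE)
  }
  deps <- list(cluster = "differential", associate = "differential")
  for (s in intersect(names(deps), stages)) {
    if (!deps[[s]] %in% stages) {
      stop(sprintf("stage '%s' requires stage '%s'", s, deps[[s]]),
           call. = FALSE)
    }
  }
  structure(list(simulate = simulate, input_dir = input_dir,
                 stages = stages,
                 species_min_abund = species_min_abund,
                 species_min_samples = species_min_samples,
                 criteria = criteria, screen_factors = screen_factors,
                 n_permutations = n_permutations,
                 r_threshold = r_threshold,
                 assoc_q_cutoff = assoc_q_cutoff,
                 assoc_p_cutoff = assoc_p_cutoff,
                 rf = utils::modifyList(list(ntree = 500, n_trials = 5,
                                             n_folds = 10, counts = NULL,
                                             n_boot = 2000), rf),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

write_stage_tsv <- function(x, outdir, name) {
  readr::write_tsv(tibble::as_tibble(x), file.path(outdir, name))
}

#' Run the full multi-omics pipeline
#'
#' Executes the enabled stages in dependency order on a simulated (or read)
#' cohort: diversity (alpha, Bray-Curtis, PCoA, PERMANOVA factor screen),
#' differential features (species, fecal and serum metabolites),
#' covariation clustering of differential fecal metabolites, species-
#' metabolite association with replication on controls, and random-forest
#' marker selection per omic. Every artifact is written as TSV/JSON under
#' `config$outdir` together with a manifest recording parameters, the seed
#' and input checksums. A fixed config (and seed) reproduces every output
#' byte-identically.
#'
#' Differential species use the same Wilcoxon/BH stack as metabolites, as a
#' stand-in for LDA-effect-size tooling.
#'
#' @param config A [pipeline_config()].
#' @return A report list (invisible components also written to disk):
#'   cohort, per-stage results, and, when ground truth is available, a
#'   `recovery` table (differential sensitivity, cluster agreement,
#'   association recall, AUC per omic).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- derive_seed(seed, "simulate")
    cohort <- generate_cohort(sim_cfg)
  } else {
    cohort <- list(
      microbiome = read_feature_table(
        file.path(config$input_dir, "microbiome.tsv"), "relative_abundance"),
      fecal_mets = read_feature_table(
        file.path(config$input_dir, "fecal_metabolites.tsv"), "intensity"),
      serum_mets = read_feature_table(
        file.path(config$input_dir, "serum_metabolites.tsv"), "intensity"),
      metadata = read_sample_metadata(
        file.path(config$input_dir, "metadata.tsv")),
      truth = NULL)
  }
  write_cohort_inputs <- file.path(config$outdir, "inputs")
  if (inherits(cohort, "momics_cohort")) write_cohort(cohort, write_cohort_inputs)

  md <- cohort$metadata
  microbiome <- filter_species(cohort$microbiome,
                               min_abund = config$species_min_abund,
                               min_samples = config$species_min_samples)
  report <- list(cohort = cohort, microbiome_filtered = microbiome)
  tables <- list(species = microbiome, fecal = cohort$fecal_mets,
                 serum = cohort$serum_mets)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  if ("diversity" %in% config$stages) {
    alpha <- alpha_diversity(microbiome)
    bc <- bray_curtis(microbiome)
    ord <- pcoa_ordination(bc, k = 2)
    screen <- factor_screen(bc, md, config$screen_factors,
                            n_permutations = config$n_permutations,
                            seed = derive_seed(seed, "permanova"))
    report$diversity <- list(alpha = alpha, bray_curtis = bc, pcoa = ord,
                             factor_screen = screen)
    write_stage_tsv(alpha, config$outdir, "alpha_diversity.tsv")
    write_stage_tsv(ord$scores, config$outdir, "pcoa_scores.tsv")
    write_stage_tsv(screen, config$outdir, "factor_screen.tsv")
    log_stage("diversity", "screened %d factors over %d samples",
              nrow(screen), nrow(alpha))
  }

  if ("differential" %in% config$stages) {
    diffs <- purrr::imap(tables, function(tab, nm) {
      differential_features(tab, md, criteria = config$criteria)
    })
    report$differential <- diffs
    for (nm in names(diffs)) {
      write_stage_tsv(diffs[[nm]], config$outdir,
                      sprintf("differential_%s.tsv", nm))
      log_stage("differential", "%s: %d/%d features pass univariate q<%g",
                nm, sum(diffs[[nm]]$passes_univariate), nrow(diffs[[nm]]),
                config$criteria$q_cutoff)
    }
  }

  passing <- function(d) {
    flag <- if (attr(d, "criteria")$mode == "combined") d$passes_combined
            else d$passes_univariate
    d$feature_id[flag]
  }

  if ("cluster" %in% config$stages) {
    d <- report$differential$fecal
    sel <- passing(d)
    if (length(sel) >= 2) {
      logged <- log_transform(smooth_zeros(cohort$fecal_mets))
      logged <- dplyr::select(logged, "sample_id", dplyr::all_of(sel))
      resid <- residualize(logged, md, phenotype = "group", age = "age")
      fc <- setNames(d$fold_change, d$feature_id)[sel]
      ranking <- sel[order(-fc, sel)]
      assignment <- greedy_cluster(resid, ranking,
                                   r_threshold = config$r_threshold)
      summ <- cluster_summary(assignment, d)
      report$cluster <- list(assignment = assignment, summary = summ)
      write_stage_tsv(assignment, config$outdir, "cluster_assignment.tsv")
      write_stage_tsv(summ, config$outdir, "cluster_summary.tsv")
      log_stage("cluster", "%d metabolites -> %d clusters", length(sel),
                max(assignment$cluster))
    } else {
      report$cluster <- NULL
      log_stage("cluster", "skipped: fewer than 2 differential metabolites")
    }
  }

  if ("associate" %in% config$stages) {
    sp_sel <- passing(report$differential$species)
    met_sel <- passing(report$differential$fecal)
    case_ids <- md$sample_id[md$group == "IBS"]
    ctrl_ids <- md$sample_id[md$group == "HC"]
    if (length(sp_sel) > 0 && length(met_sel) > 0) {
      rec <- associate(microbiome, cohort$fecal_mets, case_ids,
                       species_set = sp_sel, metabolite_set = met_sel,
                       q_cutoff = config$assoc_q_cutoff)
      rec <- replicate_associations(rec, microbiome, cohort$fecal_mets,
                                    ctrl_ids,
                                    p_cutoff = config$assoc_p_cutoff)
      report$association <- rec
      write_stage_tsv(rec, config$outdir, "associations.tsv")
      log_stage("associate", "%d pairs tested, %d discovered, %d replicated",
                nrow(rec), sum(rec$discovered), sum(rec$replicated))
    } else {
      report$association <- NULL
      log_stage("associate", "skipped: empty differential species or metabolite set")
    }
  }

  if ("classify" %in% config$stages) {
    y <- md$group[match(microbiome$sample_id, md$sample_id)]
    models <- purrr::imap(tables, function(tab, nm) {
      cts <- config$rf$counts
      if (!is.null(cts)) cts <- sort(unique(pmin(cts, ncol(tab) - 1)))
      fit_marker_model(tab, y, counts = cts,
                       n_trials = config$rf$n_trials,
                       n_folds = config$rf$n_folds,
                       ntree = config$rf$ntree, n_boot = config$rf$n_boot,
                       seed = derive_seed(seed, paste0("rf_", nm)))
    })
    report$markers <- models
    for (nm in names(models)) {
      mdl <- models[[nm]]
      write_stage_tsv(mdl$curve, config$outdir,
                      sprintf("error_curve_%s.tsv", nm))
      write_stage_tsv(tibble::tibble(feature_id = mdl$selected_features),
                      config$outdir, sprintf("markers_%s.tsv", nm))
      jsonlite::write_json(
        list(n_selected = mdl$n_selected, auc = mdl$auc,
             ci_lo = mdl$auc_ci[1], ci_hi = mdl$auc_ci[2],
             cohort = mdl$cohort),
        file.path(config$outdir, sprintf("markers_%s.json", nm)),
        auto_unbox = TRUE, digits = NA)
      log_stage("classify", "%s: %d markers, AUC %.3f", nm,
                mdl$n_selected, mdl$auc)
    }
  }

  if (!is.null(cohort$truth)) {
    report$recovery <- recovery_table(report, cohort$truth)
    write_stage_tsv(report$recovery, config$outdir, "recovery.tsv")
  }

  manifest <- list(
    package = "ibsmomics",
    version = as.character(utils::packageVersion("ibsmomics")),
    seed = seed,
    stages = config$stages,
    parameters = list(
      species_filter = c(config$species_min_abund,
                         config$species_min_samples),
      criteria = unclass(config$criteria),
      n_permutations = config$n_permutations,
      r_threshold = config$r_threshold,
      assoc_cutoffs = c(q = config$assoc_q_cutoff,
                        p = config$assoc_p_cutoff),
      rf = config$rf),
    input_md5 = if (inherits(cohort, "momics_cohort")) {
      sums <- tools::md5sum(list.files(write_cohort_inputs,
                                       full.names = TRUE))
      as.list(setNames(unname(sums), basename(names(sums))))
    } else NULL)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

# Ground-truth recovery metrics for a pipeline report.
recovery_table <- function(report, truth) {
  rows <- list()
  if (!is.null(report$differential)) {
    for (nm in names(report$differential)) {
      tr <- truth$differential_ids[truth$differential_ids$table ==
                                     c(species = "species", fecal = "fecal",
                                       serum = "serum")[nm], ]
      d <- report$differential[[nm]]
      flagged <- d$feature_id[d$passes_univariate]
      present <- intersect(tr$feature_id, d$feature_id)
      if (length(present) > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          metric = paste0("differential_sensitivity_", nm),
          value = mean(present %in% flagged))
      }
    }
  }
  if (!is.null(report$cluster) && nrow(truth$cluster_membership) > 0) {
    planted <- truth$cluster_membership
    asg <- report$cluster$assignment
    common <- intersect(planted$feature_id, asg$feature_id)
    if (length(common) >= 2) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        metric = "cluster_ari",
        value = adjusted_rand_index(
          planted$cluster[match(common, planted$feature_id)],
          asg$cluster[match(common, asg$feature_id)]))
    }
  }
  if (!is.null(report$association) && nrow(truth$association_pairs) > 0) {
    rec <- report$association
    key <- paste(rec$species_id, rec$metabolite_id)
    tkey <- paste(truth$association_pairs$species_id,
                  truth$association_pairs$metabolite_id)
    tested <- tkey %in% key
    if (any(tested)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        metric = "association_recall",
        value = mean(rec$discovered[match(tkey[tested], key)]))
    }
  }
  if (!is.null(report$markers)) {
    for (nm in names(report$markers)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        metric = paste0("auc_", nm), value = report$markers[[nm]]$auc)
    }
  }
  dplyr::bind_rows(rows)
}

#' Compare differential calls between two cohorts
#'
#' Per feature shared by the two differential tables: direction concordance
#' and the validation q-value; plus summary counts of same-direction and
#' validation-significant features, overall and restricted to discovery
#' hits.
#'
#' @param discovery,validation `diff_features` tibbles produced with
#'   identical parameters on the two cohorts.
#' @param q_cutoff FDR cutoff used for the validation-significant count.
#' @return List with `table` (per-feature tibble) and `summary` (one-row
#'   tibble of counts).
#' @export
compare_cohorts <- function(discovery, validation, q_cutoff = 0.05) {
  common <- intersect(discovery$feature_id, validation$feature_id)
  if (length(common) == 0) {
    stop("the two cohorts share no features", call. = FALSE)
  }
  d <- tibble::as_tibble(discovery)[match(common, discovery$feature_id), ]
  v <- tibble::as_tibble(validation)[match(common, validation$feature_id), ]
  tab <- tibble::tibble(
    feature_id = common,
    direction_discovery = d$direction,
    direction_validation = v$direction,
    same_direction = d$direction == v$direction,
    q_discovery = d$q_value,
    q_validation = v$q_value,
    discovery_hit = d$passes_univariate)
  summary <- tibble::tibble(
    n_common = length(common),
    n_same_direction = sum(tab$same_direction),
    n_validation_significant = sum(tab$q_validation < q_cutoff),
    n_discovery_hits = sum(tab$discovery_hit),
    n_hits_same_direction = sum(tab$same_direction & tab$discovery_hit),
    n_hits_validated = sum(tab$discovery_hit & tab$same_direction &
                             tab$q_validation < q_cutoff))
  list(table = tab, summary = summary)
}
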