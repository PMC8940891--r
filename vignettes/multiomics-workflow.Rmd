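---
title: "Microbiome-metabolome integration: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbiome-metabolome integration: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ibsmomics` re-implements, as reusable and tested components, the analysis
workflow used in integrated case-control studies of the gut microbiome and
the fecal/serum metabolome — the kind of study that profiles an IBS cohort
with shotgun metagenomics (species-level relative abundances) and untargeted
LC-MS (metabolite feature intensities) and asks which features differ
between patients and controls, how differential metabolites co-vary, which
microbes track which metabolites, and how well the profiles classify
disease. This vignette documents the statistical models, the tunable
parameters with their defaults, the synthetic-data generator that stands in
for cohort data, and the design decisions taken where the underlying
procedures are commonly under-specified.

## The workflow

```{r}
library(ibsmomics)

config <- pipeline_config(
  simulate = synth_config(n_case = 100, n_control = 60, seed = 1),
  seed = 1, outdir = "momics_run")
report <- run_pipeline(config)
```

The stages run in dependency order:

1. **Table handling and filtering** (`read_feature_table()`,
   `filter_species()`, `total_sum_scale()`). Species profiles are filtered
   by the standard prevalence rule: keep species whose relative abundance
   strictly exceeds 0.1% (`min_abund = 0.001`) in at least 6 samples. The
   verb is read strictly: a species at exactly 0.001 in exactly 6 samples
   is removed.

2. **Diversity and factor screening** (`shannon_index()`, `bray_curtis()`,
   `pcoa_ordination()`, `permanova()`, `factor_screen()`). Community
   structure is summarized by natural-log Shannon diversity and Bray-Curtis
   dissimilarity; PERMANOVA partitions the Bray-Curtis sum of squares by
   one clinical factor at a time, with significance from 1000 label
   permutations and the `(1 + hits) / (1 + permutations)` convention so p
   is never exactly zero. The screen is *marginal* — one model per factor
   with BH adjustment across factors — because per-factor variance bars
   with a per-factor FDR are what such studies report; a joint or
   sequential model would make each factor's share depend on term order.

3. **Differential features** (`differential_features()`). Per feature: a
   two-sided Wilcoxon rank-sum p (exact enumeration when both groups have
   at most 8 observations and no ties; otherwise the tie- and
   continuity-corrected normal approximation), BH q across the features of
   one table, and the fold change (case mean / control mean) on raw,
   zero-smoothed values. Two published criteria coexist and are exposed as
   modes rather than reconciled: `"univariate"` (FDR < 0.05) and
   `"combined"` (PLS-DA VIP > 1.0, FDR < 0.1, and a fold-change condition
   on the 0.8–1.2 band). The VIP is a from-scratch NIPALS PLS with a
   dummy-coded response; `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a
   SSY_a)`, whose squared values average exactly 1 — an identity the test
   suite asserts on every fit.

4. **Covariation clustering** (`smooth_zeros()`, `log_transform()`,
   `residualize()`, `greedy_cluster()`). Zeros are additively smoothed by
   half the smallest non-zero measurement *per sample*, intensities are
   log-transformed, and each feature is residualized by ordinary least
   squares on phenotype (categorical) plus age (continuous). Differential
   metabolites, ranked by fold change (descending), are scanned once:
   a feature joins the first existing cluster whose members' mean Spearman
   correlation with it strictly exceeds 0.7, else it seeds a new cluster;
   clusters are finally renumbered by size, largest first.

5. **Microbe-metabolite association** (`associate()`,
   `replicate_associations()`). All differential-species x
   differential-metabolite pairs are tested by Spearman correlation over
   the *case* samples, with BH across the full pair grid actually tested;
   discovery means q < 0.05. The replication filter then recomputes each
   pair on the *controls* and keeps pairs that are nominally significant
   (p < 0.05) with the same correlation sign — a deliberately weaker
   criterion, since controls are fewer and the claim is only that the
   relationship is not disease-specific noise.

6. **Marker selection** (`fit_marker_model()`, `evaluate_on_cohort()`).
   Features are ranked once by random-forest mean-decrease-in-impurity
   importance; the averaged error curve from 5 trials of stratified
   10-fold cross-validation is swept over nested marker counts; the
   selected panel is the smallest count whose mean error falls strictly
   below (minimum error + its standard error). Discovery AUC is computed
   from cross-validated vote fractions and reported with a stratified
   bootstrap percentile 95% CI (2000 resamples); validation cohorts are
   scored by a forest refit on the discovery samples.

## The synthetic cohort generator

No deposited cohort data are shipped or downloaded; `generate_cohort()`
produces cohorts whose *ground truth is known*, which turns every stage
into a measurable parameter-recovery problem. The generator emulates:

- **Compositional species tables.** Per-species log-normal loads (log-mean
  spread SD 2, within-species SD 1) renormalized per sample, giving the
  dominance structure the 0.1%/6-sample filter expects. Sparsity comes
  from per-species detection-limit censoring at fractions drawn from
  U[0, 0.5].
- **Metabolite intensities.** Log-normal with per-feature log-means drawn
  from U[ln 10, ln 1000] and sigma = 0.5 — a stand-in, not a claim about
  any real acquisition; untargeted LC-MS intensity distributions are not
  published in enough detail to fit.
- **Planted differentials.** A fraction (`frac_differential`, default
  0.15) of features per table receives a case-group log shift of
  `log_fold_effect` (default ln 2) with random direction.
- **Covariation clusters.** Members share a per-cluster standard-normal
  latent factor; the loading is calibrated *numerically* (bisection on a
  simulated pair) so the realized pairwise Spearman correlation of the
  censored table hits `cluster_corr`. Cluster members shift coherently
  (one direction per cluster): opposing shifts would destroy the
  correlation the cluster is defined by.
- **Species-metabolite couplings.** A coupled metabolite loads on the
  normal scores of its partner species' *observed* relative abundance, so
  the rank relationship survives compositional renormalization; the
  loading is again calibrated numerically to hit `assoc_strength` within
  cases. With `assoc_in_controls = FALSE` the coupling exists in cases
  only, which the replication filter should reject.
- **Clinical covariates.** Age uniform on 18–65; IBS subtype and
  depression-stratum frequencies mirror a 264-patient discovery cohort;
  HAMD/SDS scores are drawn inside the bands their stratum implies, so
  `stratify_depression()` reproduces the stored class exactly.

Two cohorts from one generative process (discovery/validation) are drawn
by fixing the config and varying only `noise_seed`: the planted world —
which features are differential, directions, cluster membership, coupling
pairs and signs, feature-level baselines — derives from `config$seed`
alone.

**The zero model.** Zeros are produced by censoring the lowest
`zero_inflation` fraction of each feature's intensities, i.e. a detection
limit, not by independent per-cell dropout. This is deliberate:
independent masking at a 20% rate caps the attainable Spearman correlation
between two perfectly coupled features at roughly 0.42, which would make
the generator's own contract ("cluster members correlate at
`cluster_corr`") unsatisfiable, and it is also not how missing peaks arise
in intensity data, where low-abundance ions fall below detection.
Censoring keeps the zeros concentrated in the concordant lower tail and
leaves rank correlations essentially intact.

**What a green test does not establish.** The generator's features are
conditionally independent given the planted structure; real microbiome
and metabolome data have pervasive correlation, batch structure, library-
size artifacts and non-log-normal tails. Recovery rates measured here are
upper bounds on what the same thresholds would achieve on real cohorts,
and the published headline counts (hundreds of differential metabolites,
dozens of species) depend on the deposited data and are not reproduced at
desk scale.

## Numerical and design choices

- **Fold-change band.** The combined criterion's "fold change in the range
  of 0.8–1.2" is implemented as an *exclusion* band: differential features
  must have FC <= 0.8 or >= 1.2. Requiring a fold change inside a
  near-unity band would contradict "differentially abundant"; the literal
  inclusive reading remains available via `fc_band_mode = "include"`.
- **Depression strata.** HAMD = 7 falls between the published "< 7" and
  "8–16" bands; it is resolved conservatively to no depression. The SDS
  screen (cutoff 53) precedes HAMD: a high HAMD with SDS <= 53 is still
  classed rIBS, matching a workflow in which only SDS-positive subjects
  see the psychiatrist.
- **Greedy clustering ties.** "Exceeding" the r = 0.7 threshold is strict;
  mean similarity is the *signed* mean (strong negative correlation
  repels; `similarity = "absolute"` is available); a candidate eligible
  for several clusters joins the first-created one (deterministic
  single-pass reading; `assign = "best"` is available); fold-change ties
  in the ranking break lexically by feature id.
- **Association scope.** Abundances are *not* residualized before the
  association scan (residualization belongs to the clustering stage
  only); species constant within the case samples are skipped and logged,
  never imputed, and skipped pairs leave the BH family.
- **PERMANOVA mechanics.** The pseudo-F uses the Gower-centered inner
  product matrix and a hat-matrix trace, which equals the classical
  within/among decomposition for categorical factors and extends to a
  single numeric predictor; permutations run in compiled code with a
  dedicated deterministic RNG. When a factor separates groups perfectly
  the residual sum of squares is numerically zero and is clamped so F is
  a huge finite number rather than overflowing.
- **Forest settings.** 500 trees, sqrt(p) candidate features per split,
  fully grown trees, vote-fraction probabilities with a 0.5 threshold for
  the error curves. The forest is implemented in C++ inside the package
  (no forest implementation is otherwise available in the dependency
  budget) with a platform-stable RNG, so a seed pins results exactly.
  Feature ranking is computed once on all discovery data, outside the
  cross-validation — the historical workflow for the min-plus-SE rule —
  which makes the *error curve* optimistic even though the reported AUC
  is cross-validated; a fully nested re-ranking per fold costs roughly
  `n_folds` times more and is the obvious extension.
- **Degenerate error curves.** If no count falls strictly below the
  min-plus-SE cutoff (a flat curve), the minimum-error count is returned
  with a warning; the rule is otherwise undefined there.
- **CI method.** AUC confidence intervals use the stratified bootstrap
  percentile method rather than DeLong: assumption-light and exact about
  what is resampled.
- **Seeds.** A single pipeline seed deterministically derives per-stage
  seeds by hashing stage names, so adding a stage never shifts another
  stage's stream; two runs with one seed are byte-identical on disk.

## Known limitations

Rank correlation on compositions is blind to the constant-sum constraint
(a SparCC-style estimator would be the compositionally aware choice); the
LEfSe cascade is replaced by the same Wilcoxon/BH stack used for
metabolites, which is a stand-in, not a reimplementation; UniFrac-style
phylogenetic distances and db-RDA are out of scope; and the greedy
clustering is order-sensitive by construction — the tests assert
determinism given a ranking, not invariance to it.
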