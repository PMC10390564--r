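# Study-scale cohort analysis in one call: simulate the default young/old
# cohort, preprocess, derive thresholds (knock-out-anchored p16, pooled
# young-cohort quantiles for p21/Ki67/BCL-2), call markers and compute the
# headline senescence metrics.

#' Run the default cohort analysis end to end
#'
#' Simulates `n_young` young and `n_old` old samples plus a p16-null control
#' with the default calibration, runs bead normalization, arcsinh transform
#' and cleanup gating, derives the marker thresholds, and returns per-sample
#' summaries together with the headline cohort metrics: mean per-sample
#' percentages of p16+/p21+/p16KB cells, the pooled old-cohort p16KB share
#' of p16+ cells, the pooled %Ki67- of p16+BCL-2+ cells, and the old/young
#' fold changes of %p16KB and of mean BCL-2 expression within p16+ cells.
#'
#' @param seed master seed; per-sample seeds derive from it.
#' @param n_events acquired events per sample.
#' @param n_young,n_old group sizes.
#' @param config simulation configuration (defaults to the shipped
#'   calibration).
#' @param panel antibody panel.
#' @return List with `metrics` (named numeric vector), `summary`
#'   (per-sample and group tables), `cleaned` (list of cleaned event
#'   matrices), `calls`, `thresholds`, and `design`.
#' @export
run_cohort_analysis <- function(seed = 1L, n_events = 20000,
                                n_young = 15, n_old = 12,
                                config = default_simulation_config(),
                                panel = default_panel()) {
  config$seed <- seed
  design <- default_cohort_design(n_young = n_young, n_old = n_old,
                                  n_senolytic = 0, ko_control = TRUE)
  cohort <- simulate_cohort(config, design, panel, n_events = n_events)
  cleaned <- lapply(lapply(cohort, preprocess_sample,
                           cofactor = config$cofactor), `[[`, "matrix")

  ko_id <- design$sample_id[design$genotype == "ko_control"][1]
  young_ids <- design$sample_id[design$group == "young"]
  old_ids <- design$sample_id[design$group == "old"]
  pq <- config$thresholds$pooled_quantiles
  thresholds <- threshold_set(list(
    derive_threshold(cleaned[[ko_id]], "p16", config$thresholds$ko_quantile),
    derive_pooled_threshold(cleaned[young_ids], "p21", pq[["p21"]]),
    derive_pooled_threshold(cleaned[young_ids], "BCL-2", pq[["BCL-2"]]),
    derive_pooled_threshold(cleaned[young_ids], "Ki67", pq[["Ki67"]])))
  calls <- lapply(cleaned, call_markers, thresholds = thresholds)
  summary <- summarize_calls(calls, design, cleaned)

  grp_mean <- function(metric, group) {
    g <- summary$groups
    g$mean[g$metric == metric & g$group == group]
  }
  # pooled old-cohort combinatorial shares
  old_flags <- do.call(rbind, lapply(calls[old_ids], function(cl) cl$flags))
  share_p16kb_old <- 100 * sum(old_flags$p16KB) / sum(old_flags$p16)
  parent <- old_flags$p16 & old_flags[["BCL-2"]]
  ki67neg_old <- 100 * sum(parent & !old_flags$Ki67) / sum(parent)

  metrics <- c(
    pct_p16_young = grp_mean("pct_p16", "young"),
    pct_p16_old = grp_mean("pct_p16", "old"),
    pct_p21_young = grp_mean("pct_p21", "young"),
    share_p16kb_of_p16_old = share_p16kb_old,
    pct_ki67neg_of_p16bcl2_old = ki67neg_old,
    pct_p16kb_young = grp_mean("pct_p16kb", "young"),
    pct_p16kb_old = grp_mean("pct_p16kb", "old"),
    fold_p16kb_old_vs_young =
      grp_mean("pct_p16kb", "old") / grp_mean("pct_p16kb", "young"),
    fold_bcl2_in_p16_old_vs_young =
      grp_mean("mean_bcl2_in_p16", "old") / grp_mean("mean_bcl2_in_p16", "young")
  )
  list(metrics = metrics, summary = summary, cleaned = cleaned,
       calls = calls, thresholds = thresholds, design = design)
}

#' Recover the mesenchymal population structure from a pooled simulation
#'
#' Simulates one large default-mixture sample, cleans it, subsamples the
#' requested number of events, runs the 10x10 SOM with hierarchical-consensus
#' metaclustering at `k = 11` (10 iterations) on the identity channels, and
#' annotates the metaclusters with the shipped population rules.
#'
#' @param seed master seed.
#' @param n_pooled cleaned events used for clustering.
#' @param k metacluster count.
#' @param config,panel simulation configuration and panel.
#' @return List with `n_labels` (distinct non-`unlabeled` populations),
#'   `metaclusters`, and the cleaned pooled matrix.
#' @export
run_population_recovery <- function(seed = 1L, n_pooled = 50000, k = 11,
                                    config = default_simulation_config(),
                                    panel = default_panel()) {
  sample_seed <- .stable_seed(seed, "population_recovery")
  raw <- simulate_sample(config, "young", sample_seed, panel,
                         n_events = ceiling(n_pooled * 1.25),
                         sample_id = "pooled_mixture")
  cleaned <- preprocess_sample(raw, cofactor = config$cofactor)$matrix
  pooled <- subsample_events(cleaned, n_pooled, seed = sample_seed)
  som <- train_som(pooled, grid = c(10, 10), epochs = 10, seed = seed)
  mc <- consensus_metacluster(som, pooled, k = k, iterations = 10,
                              seed = seed)
  mc <- annotate_clusters(mc, load_annotation_rules(), pooled)
  list(n_labels = length(setdiff(unique(mc$annotation), "unlabeled")),
       metaclusters = mc, pooled = pooled)
}

#' Select the senescence-archetype cluster count from gated p16+ cells
#'
#' Pools the gated p16+ events of a cleaned cohort, trains a 10x10 SOM on
#' the senescence-panel channels and picks `k` by mean silhouette over the
#' candidate range.
#'
#' @param cleaned named list of cleaned event matrices (young + old cohort).
#' @param calls matching marker calls.
#' @param design cohort design (knock-out controls are excluded).
#' @param k_range candidate metacluster counts.
#' @param seed integer seed.
#' @return List with `k` (chosen), the silhouette table, and the pooled
#'   p16+ matrix.
#' @export
run_archetype_selection <- function(cleaned, calls, design, k_range = 2:10,
                                    seed = 1L) {
  wt_ids <- design$sample_id[design$genotype != "ko_control"]
  p16pos <- lapply(wt_ids, function(s) {
    .subset_events(cleaned[[s]], calls[[s]]$flags$p16)
  })
  pooled <- pool_events(p16pos)
  channels <- senescence_panel_markers(pooled$panel)
  som <- train_som(pooled, channels = channels, grid = c(10, 10),
                   epochs = 10, seed = seed)
  sel <- select_k(som, pooled, k_range = k_range, iterations = 10,
                  seed = seed)
  list(k = sel$k, table = sel$table, pooled = pooled, som = som)
}
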