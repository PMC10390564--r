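# End-to-end pipeline: simulate -> preprocess -> gate -> cluster -> diff ->
# citrus -> report, driven by one run configuration, with seeding,
# per-artifact digests and a run manifest.

#' Default run configuration
#'
#' @param out_dir output directory for artifacts.
#' @param seed master seed.
#' @return A run-configuration list (see [run_pipeline()]).
#' @export
default_run_config <- function(out_dir = tempfile("senocyto_run_"),
                               seed = 1L) {
  list(
    out_dir = out_dir,
    seed = seed,
    stages = list(simulate = TRUE, preprocess = TRUE, gate = TRUE,
                  cluster = TRUE, diff = TRUE, citrus = TRUE, report = TRUE),
    simulate = list(events_per_sample = 5000, n_young = 6, n_old = 6,
                    n_senolytic = 6),
    preprocess = list(cofactor = 5, n_bins = 20),
    gate = list(),
    cluster = list(grid = c(10, 10), k = 11, iterations = 10,
                   events_per_sample = 2000),
    diff = list(reference = "young", comparison = "old"),
    citrus = list(events_per_sample = 200, min_fraction = 0.02,
                  fdr = 0.05, permutations = 500,
                  reference = "old", comparison = "old_senolytic",
                  cv_folds = 5),  # fold count recorded for provenance only
    report = list()
  )
}

#' Load a run configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_run_config()].
#'
#' @param path YAML run config.
#' @return Run-configuration list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]])) {
        merge_in(base[[nm]], upd[[nm]])
      } else upd[[nm]]
    }
    base
  }
  merge_in(cfg, user)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in fixed order on a simulated cohort, writes
#' stage artifacts (TSV/YAML/JSON) under `config$out_dir`, and returns a
#' manifest recording, per stage, its status, parameters, outputs and MD5
#' digests. Stage dependencies are validated before execution: gating needs
#' preprocessing, differential statistics and the report need gating, and
#' clustering-dependent stages need clustering.
#'
#' @param config run configuration (see [default_run_config()]).
#' @return The run manifest (list), invisibly written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = default_run_config()) {
  st <- config$stages
  if (isTRUE(st$gate) && !isTRUE(st$preprocess)) {
    stop("validation error: gate stage requires preprocess")
  }
  if (isTRUE(st$diff) && !isTRUE(st$gate)) {
    stop("validation error: diff stage requires gate")
  }
  if (isTRUE(st$report) && !isTRUE(st$gate)) {
    stop("validation error: report stage requires gate")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  artifacts <- character(0)
  note <- function(stage, status, params = NULL, outputs = character(0)) {
    digests <- if (length(outputs)) {
      as.list(tools::md5sum(outputs))
    } else list()
    manifest$stages[[stage]] <<- list(status = status, parameters = params,
                                      outputs = as.list(outputs),
                                      digests = digests)
    artifacts <<- c(artifacts, outputs)
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e))
    })
  }

  panel <- default_panel()
  simcfg <- default_simulation_config()
  simcfg$seed <- config$seed

  # ---- simulate -----------------------------------------------------------
  if (!isTRUE(st$simulate)) {
    stop("validation error: pipeline runs start from the simulate stage")
  }
  sim <- config$simulate
  design <- default_cohort_design(sim$n_young, sim$n_old, sim$n_senolytic)
  cohort <- run_stage("simulate", function() {
    simulate_cohort(simcfg, design, panel, n_events = sim$events_per_sample)
  })
  design_path <- file.path(config$out_dir, "design.tsv")
  write_cohort_design(design, design_path)
  truth_path <- file.path(config$out_dir, "truth_summary.tsv")
  utils::write.table(truth_summary(cohort), truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("simulate", "complete", sim, c(design_path, truth_path))

  # ---- preprocess ---------------------------------------------------------
  cleaned <- NULL
  qc_path <- file.path(config$out_dir, "qc_report.tsv")
  if (isTRUE(st$preprocess)) {
    pp <- config$preprocess
    res <- run_stage("preprocess", function() {
      lapply(cohort, preprocess_sample, cofactor = pp$cofactor,
             n_bins = pp$n_bins)
    })
    cleaned <- lapply(res, `[[`, "matrix")
    qc <- do.call(rbind, lapply(names(res), function(s) {
      cbind(sample_id = s, res[[s]]$qc)
    }))
    utils::write.table(qc, qc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("preprocess", "complete", pp, qc_path)
  } else {
    note("preprocess", "skipped")
  }

  # ---- gate ---------------------------------------------------------------
  calls <- summary_tab <- thresholds <- NULL
  if (isTRUE(st$gate)) {
    res <- run_stage("gate", function() {
      ko_id <- design$sample_id[design$genotype == "ko_control"][1]
      young_ids <- design$sample_id[design$group == "young"]
      thr <- threshold_set(list(
        derive_threshold(cleaned[[ko_id]], "p16",
                         simcfg$thresholds$ko_quantile),
        derive_pooled_threshold(cleaned[young_ids], "p21",
                                simcfg$thresholds$pooled_quantiles[["p21"]]),
        derive_pooled_threshold(cleaned[young_ids], "BCL-2",
                                simcfg$thresholds$pooled_quantiles[["BCL-2"]]),
        derive_pooled_threshold(cleaned[young_ids], "Ki67",
                                simcfg$thresholds$pooled_quantiles[["Ki67"]])))
      cl <- lapply(cleaned, call_markers, thresholds = thr)
      list(thresholds = thr, calls = cl,
           summary = summarize_calls(cl, design, cleaned))
    })
    thresholds <- res$thresholds
    calls <- res$calls
    summary_tab <- res$summary
    thr_path <- file.path(config$out_dir, "thresholds.yaml")
    write_thresholds(thresholds, thr_path)
    sum_path <- file.path(config$out_dir, "call_summary.tsv")
    utils::write.table(summary_tab$samples, sum_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("gate", "complete", NULL, c(thr_path, sum_path))
  } else {
    note("gate", "skipped")
  }

  # ---- cluster ------------------------------------------------------------
  mc <- pooled <- NULL
  if (isTRUE(st$cluster)) {
    cc <- config$cluster
    res <- run_stage("cluster", function() {
      wt_ids <- design$sample_id[design$genotype != "ko_control"]
      pooled <- pool_events(cleaned[wt_ids],
                            n_per_sample = cc$events_per_sample,
                            seed = config$seed)
      som <- train_som(pooled, grid = unlist(cc$grid), seed = config$seed)
      mc <- consensus_metacluster(som, pooled, k = cc$k,
                                  iterations = cc$iterations,
                                  seed = config$seed)
      mc <- annotate_clusters(mc, load_annotation_rules(), pooled)
      list(pooled = pooled, mc = mc)
    })
    pooled <- res$pooled
    mc <- res$mc
    ab <- cluster_abundance(mc, pooled$sample)
    ab_path <- file.path(config$out_dir, "cluster_abundance.tsv")
    utils::write.table(ab, ab_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    prof_path <- file.path(config$out_dir, "cluster_profiles.tsv")
    prof <- data.frame(cluster = seq_len(nrow(mc$profiles)),
                       label = mc$annotation, mc$profiles,
                       check.names = FALSE)
    utils::write.table(prof, prof_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("cluster", "complete", cc, c(ab_path, prof_path))
  } else {
    note("cluster", "skipped")
  }

  # ---- diff ---------------------------------------------------------------
  if (isTRUE(st$diff)) {
    dd <- config$diff
    diff_tab <- run_stage("diff", function() {
      s <- summary_tab$samples
      metrics <- c("pct_p16", "pct_p21", "pct_p16kb", "pct_p21kb")
      rows <- lapply(metrics, function(mt) {
        a <- s[[mt]][s$group == dd$reference]
        b <- s[[mt]][s$group == dd$comparison]
        cmp <- suppressWarnings(compare_groups(a, b, unit = mt))
        cmp
      })
      tab <- do.call(rbind, rows)
      tab$p_adjusted <- holm_sidak(tab$p_raw)$p_adjusted
      tab
    })
    diff_path <- file.path(config$out_dir, "differential.tsv")
    utils::write.table(diff_tab, diff_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("diff", "complete", dd, diff_path)
  } else {
    note("diff", "skipped")
  }

  # ---- citrus -------------------------------------------------------------
  citrus_sig <- NULL
  if (isTRUE(st$citrus)) {
    cz <- config$citrus
    res <- run_stage("citrus", function() {
      arm_ids <- design$sample_id[design$group %in%
                                    c(cz$reference, cz$comparison)]
      h <- build_hierarchy(cleaned[arm_ids],
                           n_per_sample = cz$events_per_sample,
                           min_fraction = cz$min_fraction,
                           seed = config$seed)
      feats <- extract_features(h, "abundance")
      assoc <- sam_association(feats, design, target_fdr = cz$fdr,
                               n_permutations = cz$permutations,
                               seed = config$seed)
      sig <- summarize_cleared_clusters(assoc, h, feats,
                                        load_annotation_rules())
      list(assoc = assoc, sig = sig)
    })
    citrus_sig <- res$sig
    cit_path <- file.path(config$out_dir, "citrus_significant.tsv")
    utils::write.table(res$assoc$results, cit_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("citrus", "complete", cz, cit_path)
  } else {
    note("citrus", "skipped")
  }

  # ---- report -------------------------------------------------------------
  if (isTRUE(st$report)) {
    report <- list(
      seed = config$seed,
      groups = if (!is.null(summary_tab)) summary_tab$groups else NULL,
      clusters = if (!is.null(mc)) {
        list(k = mc$k, labels = mc$annotation)
      } else NULL,
      citrus = if (isTRUE(st$citrus)) {
        list(n_significant = if (is.null(citrus_sig)) 0 else nrow(citrus_sig))
      } else NULL
    )
    rep_path <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(report, rep_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
    note("report", "complete", NULL, rep_path)
  } else {
    note("report", "skipped")
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
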