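# Gate expressions, subset profiling, cluster burden and clearance calls.

test_that("gate expressions parse, evaluate and report errors by position", {
  flags <- data.frame(p16 = c(TRUE, TRUE, FALSE, FALSE),
                      Ki67 = c(TRUE, FALSE, TRUE, FALSE),
                      `BCL-2` = c(TRUE, TRUE, TRUE, TRUE),
                      check.names = FALSE)
  calls <- structure(list(flags = flags, sample_id = "s", n = 4),
                     class = "senocyto_calls")
  g <- parse_gate("p16 AND NOT Ki67 AND BCL-2")
  expect_equal(senocyto:::.eval_gate(g, calls), c(FALSE, TRUE, FALSE, FALSE))
  g2 <- parse_gate("(p16 OR Ki67) AND NOT (p16 AND Ki67)")
  expect_equal(senocyto:::.eval_gate(g2, calls), c(FALSE, TRUE, TRUE, FALSE))
  labs <- c("A", "A", "B", "B")
  g3 <- parse_gate('p16 AND cluster:"A"')
  expect_equal(senocyto:::.eval_gate(g3, calls, labs),
               c(TRUE, TRUE, FALSE, FALSE))

  expect_error(parse_gate("p16 AND"), "position")
  expect_error(parse_gate("p16 ) Ki67"), "position")
  expect_error(parse_gate("p16 & Ki67"), "unexpected character")
  expect_error(senocyto:::.eval_gate(parse_gate("nosuchflag"), calls),
               "undefined flag")
})

test_that("subset algebra matches exact set intersection", {
  flags <- data.frame(a = rep(c(TRUE, FALSE), each = 10),
                      b = rep(c(TRUE, FALSE), times = 10))
  calls <- structure(list(flags = flags, sample_id = "s", n = 20),
                     class = "senocyto_calls")
  both <- senocyto:::.eval_gate(parse_gate("a AND b"), calls)
  expect_equal(which(both), intersect(which(flags$a), which(flags$b)))
  either <- senocyto:::.eval_gate(parse_gate("a OR b"), calls)
  expect_equal(which(either), sort(union(which(flags$a), which(flags$b))))
})

test_that("profiles equal brute-force filtering and averaging", {
  panel <- tiny_panel(c("p16", "IL-6"), c("senescence", "sasp"))
  set.seed(40)
  vals <- cbind(rnorm(200, 1), rnorm(200, 2))
  m <- toy_events(vals, panel, sample_id = "s1")
  thr <- threshold_set(list(list(marker = "p16", cutoff = 1, source = "manual"),
                            list(marker = "IL-6", cutoff = 2, source = "manual")))
  calls <- call_markers(m, thr)
  prof <- profile_subset(m, calls, "p16", markers = "IL-6")
  sel <- vals[, 1] > 1
  expect_equal(prof$`mean_IL-6`, mean(vals[sel, 2]))
  expect_equal(prof$`pctpos_IL-6`, 100 * mean(vals[sel, 2] > 2))
  expect_equal(prof$n_subset, sum(sel))
})

test_that("p16KB cells show the senescence-marker enrichment they were given", {
  cfg <- default_simulation_config()
  res <- sim_sample_clean("old", seed = 44, n = 20000)
  m <- res$matrix
  thr <- threshold_set(list(
    list(marker = "p16", cutoff = 1.2, source = "manual"),
    list(marker = "Ki67", cutoff = 1.4, source = "manual"),
    list(marker = "BCL-2", cutoff = 1.4, source = "manual")))
  calls <- call_markers(m, thr)
  sasp <- c("IL-1a", "IL-1b", "pNFkB", "CXCL1", "pATM")
  kb <- profile_subset(m, calls, "p16KB", markers = sasp)
  notp16 <- profile_subset(m, calls, "NOT p16", markers = sasp)
  for (mk in sasp) {
    expect_gt(kb[[paste0("mean_", mk)]], notp16[[paste0("mean_", mk)]])
  }
})

test_that("empty subsets are excluded with a warning", {
  panel <- tiny_panel("p16")
  m <- toy_events(matrix(0, 10, 1), panel, sample_id = "s1")
  thr <- threshold_set(list(list(marker = "p16", cutoff = 1, source = "manual")))
  calls <- call_markers(m, thr)
  expect_warning(out <- profile_subset(m, calls, "p16", markers = "p16"),
                 "empty")
  expect_equal(nrow(out), 0L)
})

# fabricate a metaclusters object from truth populations: lets burden and
# clearance logic be tested against known cluster memberships without a SOM
truth_metaclusters <- function(pooled) {
  pops <- sort(unique(stats::na.omit(pooled$truth$population)))
  meta <- match(pooled$truth$population, pops)
  meta[is.na(meta)] <- length(pops)  # park contaminant stragglers in one pop
  structure(list(metacluster = meta, k = length(pops),
                 annotation = pops,
                 sizes = tabulate(meta, length(pops))),
            class = "senocyto_metaclusters")
}

test_that("per-cluster senescent burden ranks follow the configured enrichment", {
  cfg <- default_simulation_config()
  design <- cohort_design(data.frame(
    sample_id = c(sprintf("y%d", 1:5), sprintf("o%d", 1:5)),
    age_group = rep(c("young", "old"), each = 5),
    treatment = rep(c("none", "vehicle"), each = 5),
    genotype = "wildtype"))
  cohort <- simulate_cohort(cfg, design, n_events = 8000)
  cleaned <- lapply(lapply(cohort, preprocess_sample), `[[`, "matrix")
  pooled <- pool_events(cleaned)
  thr <- threshold_set(list(
    list(marker = "p16", cutoff = 1.2, source = "manual"),
    list(marker = "Ki67", cutoff = 1.4, source = "manual"),
    list(marker = "BCL-2", cutoff = 1.4, source = "manual")))
  calls <- call_markers(pooled, thr)
  mc <- truth_metaclusters(pooled)
  cb <- cluster_burden(pooled, calls, mc, design)
  expect_equal(nrow(cb$burden), mc$k * nrow(design))
  # mean %p16KB per cluster tracks the configured senescence enrichment
  enrich <- vapply(cfg$populations, function(p) p$enrichment, numeric(1))
  names(enrich) <- vapply(cfg$populations, `[[`, "", "name")
  old_rows <- cb$burden[cb$burden$group == "old", ]
  mean_kb <- tapply(old_rows$pct_p16kb, old_rows$label, mean)
  shared <- intersect(names(mean_kb), names(enrich))
  expect_gte(spearman(mean_kb[shared], enrich[shared]), 0.9)
  # the two most enriched populations carry the top burden
  top2 <- names(sort(mean_kb, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("Late Osteoblasts/Osteocytes",
                          "CD24high Osteolineage"))
})

test_that("clearance reporting labels depleted clusters and spares stable ones", {
  cfg <- default_simulation_config()
  design <- cohort_design(data.frame(
    sample_id = c(sprintf("o%d", 1:6), sprintf("t%d", 1:6)),
    age_group = "old",
    treatment = rep(c("vehicle", "senolytic"), each = 6),
    genotype = "wildtype"))
  cohort <- simulate_cohort(cfg, design, n_events = 8000)
  cleaned <- lapply(lapply(cohort, preprocess_sample), `[[`, "matrix")
  pooled <- pool_events(cleaned)
  mc <- truth_metaclusters(pooled)
  ab <- cluster_abundance(mc, pooled$sample)
  rep_tab <- clearance_report(ab, design)
  cleared <- rep_tab$label[rep_tab$direction == "cleared"]
  expect_true("CD24high Osteolineage" %in% cleared)
  expect_false("LeptinR+ BMSCs" %in% cleared)
  # log2FC agrees with the generic fold-change helper per cluster
  ab$group <- design$group[match(ab$sample_id, design$sample_id)]
  for (ki in unique(rep_tab$cluster)[1:3]) {
    sub <- ab[ab$cluster == ki, ]
    fc <- group_fold_change(data.frame(sample_id = sub$sample_id,
                                       group = sub$group,
                                       fraction = sub$fraction),
                            "fraction", "old", "old_senolytic")
    expect_equal(rep_tab$log2_fold_change[rep_tab$cluster == ki],
                 fc$log2_fold, tolerance = 1e-12)
  }

  # identical arms -> everything unchanged
  ab_same <- ab[ab$group == "old", ]
  ab_same2 <- ab_same
  ab_same2$sample_id <- paste0(ab_same2$sample_id, "_dup")
  design_same <- cohort_design(data.frame(
    sample_id = c(ab_same$sample_id[!duplicated(ab_same$sample_id)],
                  unique(ab_same2$sample_id)),
    age_group = "old",
    treatment = rep(c("vehicle", "senolytic"),
                    times = c(length(unique(ab_same$sample_id)),
                              length(unique(ab_same2$sample_id)))),
    genotype = "wildtype"))
  both <- rbind(ab_same[, c("sample_id", "cluster", "fraction")],
                ab_same2[, c("sample_id", "cluster", "fraction")])
  rep_same <- clearance_report(both, design_same)
  expect_true(all(rep_same$direction == "unchanged"))
})
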