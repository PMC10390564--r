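# Threshold derivation, marker calls, combinatorial classes and summaries.

test_that("control-derived thresholds match the interpolated quantile oracle", {
  panel <- tiny_panel("p16")
  const <- toy_events(matrix(rep(2.5, 50), ncol = 1), panel,
                      sample_id = "ko")
  for (q in c(0.5, 0.9, 0.999)) {
    expect_equal(derive_threshold(const, "p16", q)$cutoff, 2.5)
  }
  vals <- seq(0.1, 1.0, by = 0.1)
  ctl <- toy_events(matrix(vals, ncol = 1), panel, sample_id = "ko")
  thr <- derive_threshold(ctl, "p16", 0.999)
  # sort-and-interpolate oracle (type-7 definition)
  h <- (10 - 1) * 0.999 + 1
  oracle <- vals[floor(h)] + (h - floor(h)) * (vals[ceiling(h)] - vals[floor(h)])
  expect_equal(thr$cutoff, oracle)
  expect_lte(derive_threshold(ctl, "p16", 0.90)$cutoff,
             derive_threshold(ctl, "p16", 0.999)$cutoff)
  expect_equal(thr$source, "ko_control")
  expect_equal(thr$control_sample_id, "ko")

  empty <- toy_events(matrix(numeric(0), ncol = 1), panel)
  expect_error(derive_threshold(empty, "p16", 0.999), "empty")
  expect_error(derive_threshold(ctl, "nonexistent", 0.9), "not in panel")
})

test_that("threshold sets keep provenance and survive YAML round-trips", {
  panel <- tiny_panel("p16")
  ctl <- toy_events(matrix(seq(0, 1, length.out = 20), ncol = 1), panel,
                    sample_id = "ko")
  thr <- threshold_set(list(derive_threshold(ctl, "p16", 0.99)))
  path <- tempfile(fileext = ".yaml")
  write_thresholds(thr, path)
  back <- read_thresholds(path)
  expect_equal(back$p16$cutoff, thr$p16$cutoff)
  expect_equal(back$p16$source, "ko_control")
  expect_error(threshold_set(list(list(marker = "x", cutoff = 1,
                                       source = "ko_control"))),
               "control_sample_id")
})

test_that("combinatorial class logic holds over the exhaustive truth table", {
  panel <- tiny_panel(c("p16", "Ki67", "BCL-2", "p21"))
  combos <- expand.grid(p16 = c(0, 1), Ki67 = c(0, 1), bcl2 = c(0, 1),
                        p21 = c(0, 1))
  vals <- as.matrix(combos) * 2  # positive = 2, negative = 0 vs cutoff 1
  m <- toy_events(vals, panel)
  thr <- threshold_set(list(
    list(marker = "p16", cutoff = 1, source = "manual"),
    list(marker = "Ki67", cutoff = 1, source = "manual"),
    list(marker = "BCL-2", cutoff = 1, source = "manual"),
    list(marker = "p21", cutoff = 1, source = "manual")))
  calls <- call_markers(m, thr)
  f <- calls$flags
  expect_equal(f$p16KB, combos$p16 == 1 & combos$Ki67 == 0 & combos$bcl2 == 1)
  expect_equal(f$p21KB, combos$p21 == 1 & combos$Ki67 == 0 & combos$bcl2 == 1)
  # triple-positive cell is p16+ but not p16KB
  row <- which(combos$p16 == 1 & combos$Ki67 == 1 & combos$bcl2 == 1)[1]
  expect_true(f$p16[row] && !f$p16KB[row])
})

test_that("raising a cutoff never increases the positive count", {
  panel <- tiny_panel("p16")
  set.seed(9)
  m <- toy_events(matrix(rnorm(500, 1, 1), ncol = 1), panel)
  counts <- vapply(seq(0, 2, by = 0.25), function(cut) {
    thr <- threshold_set(list(list(marker = "p16", cutoff = cut,
                                   source = "manual")))
    sum(call_markers(m, thr)$flags$p16)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("strict inequality makes cutoff-valued events negative", {
  panel <- tiny_panel("p16")
  m <- toy_events(matrix(c(0.99, 1.0, 1.01), ncol = 1), panel)
  thr <- threshold_set(list(list(marker = "p16", cutoff = 1, source = "manual")))
  expect_equal(call_markers(m, thr)$flags$p16, c(FALSE, FALSE, TRUE))
})

test_that("summaries match brute-force counting and the printed arithmetic", {
  panel <- tiny_panel(c("p16", "Ki67", "BCL-2"))
  n <- 1000
  vals <- matrix(0, n, 3)
  vals[1:76, 1] <- 2                       # 76 p16+ of 1000 -> 7.6%
  vals[1:13, 3] <- 2                       # 13 of the p16+ are BCL-2+
  vals[1, 2] <- 2                          # 1 of those is Ki67+
  m <- toy_events(vals, panel)
  thr <- threshold_set(list(
    list(marker = "p16", cutoff = 1, source = "manual"),
    list(marker = "Ki67", cutoff = 1, source = "manual"),
    list(marker = "BCL-2", cutoff = 1, source = "manual")))
  calls <- call_markers(m, thr)
  s <- summarize_calls(list(calls))
  expect_equal(s$samples$pct_p16, 7.6)
  expect_equal(s$samples$pct_p16kb, 100 * 12 / 1000)
  expect_equal(s$samples$share_p16kb_of_p16, 100 * 12 / 76)
  expect_equal(s$samples$pct_ki67neg_of_p16bcl2, 100 * 12 / 13)
  # brute force over the flag table
  f <- calls$flags
  expect_equal(s$samples$pct_p16, 100 * sum(f$p16) / nrow(f))
})

test_that("share of a 100-cell parent gate follows the printed convention", {
  panel <- tiny_panel(c("p16", "Ki67", "BCL-2"))
  vals <- matrix(0, 500, 3)
  vals[1:100, 1] <- 2
  vals[1:17, 3] <- 2   # 17 p16KB of 100 p16+ -> 17%
  m <- toy_events(vals, panel)
  thr <- threshold_set(list(
    list(marker = "p16", cutoff = 1, source = "manual"),
    list(marker = "Ki67", cutoff = 1, source = "manual"),
    list(marker = "BCL-2", cutoff = 1, source = "manual")))
  s <- summarize_calls(list(call_markers(m, thr)))
  expect_equal(s$samples$share_p16kb_of_p16, 17)
})

test_that("group fold changes behave like ratios of means", {
  samples <- data.frame(
    sample_id = letters[1:6],
    group = rep(c("young", "old"), each = 3),
    pct_p16kb = c(0.1, 0.1, 0.1, 0.68, 0.68, 0.68))
  fc <- group_fold_change(samples, "pct_p16kb", "young", "old")
  expect_equal(fc$fold, 6.8)
  expect_equal(fc$log2_fold, log2(6.8))
  same <- group_fold_change(samples, "pct_p16kb", "young", "young")
  expect_equal(same$fold, 1)
  expect_equal(same$log2_fold, 0)
  # reciprocal property
  rev <- group_fold_change(samples, "pct_p16kb", "old", "young")
  expect_equal(fc$fold * rev$fold, 1)
  samples$pct_p16kb[1:3] <- 0
  expect_warning(z <- group_fold_change(samples, "pct_p16kb", "young", "old"),
                 "zero")
  expect_true(is.na(z$fold) && is.infinite(z$log2_fold))
})

test_that("a knock-out threshold yields the expected false-positive rate", {
  cfg <- default_simulation_config()
  ko1 <- sim_ko <- simulate_sample(cfg, "young", 31, n_events = 20000,
                                   ko_control = TRUE)
  ko2 <- simulate_sample(cfg, "young", 32, n_events = 20000,
                         ko_control = TRUE)
  c1 <- preprocess_sample(ko1)$matrix
  c2 <- preprocess_sample(ko2)$matrix
  q <- 0.999
  thr <- threshold_set(list(derive_threshold(c1, "p16", q)))
  fpr <- mean(call_markers(c2, thr)$flags$p16)
  # ~1 - q on an independent knock-out sample (binomial slack at n~17k)
  expect_lt(abs(fpr - (1 - q)), 4 * sqrt(q * (1 - q) / n_events(c2)) + 5e-4)
})

test_that("gated %p16+ recovers simulated truth with small error", {
  cfg <- default_simulation_config()
  design <- cohort_design(data.frame(
    sample_id = c(sprintf("y%d", 1:3), sprintf("o%d", 1:3), "ko"),
    age_group = c(rep("young", 3), rep("old", 3), "young"),
    treatment = c(rep("none", 3), rep("vehicle", 3), "none"),
    genotype = c(rep("wildtype", 6), "ko_control")))
  cohort <- simulate_cohort(cfg, design, n_events = 20000)
  cleaned <- lapply(lapply(cohort, preprocess_sample), `[[`, "matrix")
  thr <- threshold_set(list(
    derive_threshold(cleaned$ko, "p16", cfg$thresholds$ko_quantile)))
  calls <- lapply(cleaned, call_markers, thresholds = thr)
  s <- summarize_calls(calls, design)
  truth <- truth_summary(cohort)
  merged <- merge(s$samples, truth, by = "sample_id")
  merged <- merged[merged$sample_id != "ko", ]
  expect_lt(mean(abs(merged$pct_p16.x - merged$pct_p16.y)), 0.5)
})
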