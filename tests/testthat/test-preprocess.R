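# Drift normalization, arcsinh transform, cleanup gating, subsampling.

test_that("arcsinh transform matches the closed form and is monotone", {
  panel <- tiny_panel(c("a", "b"))
  m <- event_matrix(cbind(c(0, 5, 10), c(1, 2, 3)), panel)
  t1 <- arcsinh_transform(m, cofactor = 5)
  expect_equal(unname(t1$values[1, 1]), 0)
  expect_equal(unname(t1$values[2, 1]), asinh(1), tolerance = 1e-4)  # 0.8814
  expect_true(t1$transformed)
  expect_error(arcsinh_transform(t1), "already")

  set.seed(3)
  x <- sort(abs(rnorm(50, 20, 15)))
  tx <- asinh(x / 5)
  expect_true(all(diff(tx) >= 0))
})

test_that("bead normalization equalizes injected linear drift", {
  cfg <- default_simulation_config()
  cfg$drift_slope <- 0.2
  m <- simulate_sample(cfg, "young", 9, n_events = 15000)
  norm <- bead_normalize(m, n_bins = 20)
  expect_equal(n_events(norm), n_events(m))
  # bead-channel bin medians equal within 1% after correction
  panel <- m$panel
  bead_col <- which(panel$channels$category == "instrument_bead")
  is_bead <- m$truth$class == "bead"
  bins <- ceiling(seq_len(n_events(m)) / (n_events(m) / 20))
  med <- tapply(norm$values[is_bead, bead_col], bins[is_bead], median)
  expect_lt((max(med) - min(med)) / stats::median(med), 0.01)
  # uncorrected medians show the drift
  med0 <- tapply(m$values[is_bead, bead_col], bins[is_bead], median)
  expect_gt((max(med0) - min(med0)) / stats::median(med0), 0.1)
})

test_that("bead normalization is a no-op without drift or without beads", {
  cfg <- default_simulation_config()
  cfg$drift_slope <- 0
  cfg$signals$bead_raw_cv <- 0
  m <- simulate_sample(cfg, "young", 2, n_events = 8000)
  norm <- bead_normalize(m)
  expect_equal(norm$values, m$values, tolerance = 1e-12)

  cfg$contamination$beads <- 0
  m2 <- simulate_sample(cfg, "young", 2, n_events = 2000)
  expect_warning(norm2 <- bead_normalize(m2), "fewer bead events")
  expect_identical(norm2$values, m2$values)
})

test_that("cleanup gating keeps nearly everything when nothing is dirty", {
  cfg <- default_simulation_config()
  cfg$contamination <- list(beads = 0, doublets = 0, dead = 0, debris = 0,
                            cd45pos = 0)
  m <- simulate_sample(cfg, "young", 4, n_events = 10000)
  res <- suppressWarnings(preprocess_sample(m))  # no beads to anchor on
  expect_gte(n_events(res$matrix) / n_events(m), 0.99)
})

test_that("cleanup recalls and precisely removes each contamination class", {
  cfg <- default_simulation_config()
  m <- simulate_sample(cfg, "old", 5, n_events = 12000)
  t1 <- arcsinh_transform(bead_normalize(m))
  params <- default_cleanup_params(t1)
  out <- cleanup_gate(t1, params)

  # reconstruct which events each stage removed
  truth <- t1$truth
  stage_class <- list(
    bead_removal = "bead",
    singlet_selection = c("doublet", "debris"),
    viability = "dead",
    lin_cd45_negative = "cd45pos"
  )
  surviving <- rep(TRUE, n_events(t1))
  v <- t1$values
  panel <- t1$panel
  bead_cols <- which(panel$channels$category == "instrument_bead")
  keep1 <- v[, bead_cols] <= params$bead_min
  dna <- v[, which(panel$channels$category == "instrument_dna")]
  el <- v[, which(panel$channels$category == "instrument_event_length")]
  keep2 <- dna >= params$dna_bounds[1] & dna <= params$dna_bounds[2] &
    el <= params$event_length_max
  keep3 <- v[, which(panel$channels$category == "instrument_viability")] <=
    params$viability_max
  cd45 <- v[, senocyto:::.marker_col(panel, "CD45")]
  lin <- v[, setdiff(which(panel$channels$category == "lineage"),
                     senocyto:::.marker_col(panel, "CD45"))]
  keep4 <- cd45 <= params$cd45_max & lin <= params$lineage_max
  keeps <- list(keep1, keep2, keep3, keep4)
  for (si in seq_along(stage_class)) {
    removed_here <- surviving & !keeps[[si]]
    surviving <- surviving & keeps[[si]]
    is_class <- truth$class %in% stage_class[[si]]
    recall <- sum(removed_here & is_class) / sum(is_class & {
      # events of this class still alive entering the stage
      alive_enter <- Reduce(`&`, keeps[seq_len(si - 1)], rep(TRUE, length(keep1)))
      alive_enter
    })
    precision <- sum(removed_here & is_class) / max(sum(removed_here), 1)
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.95)
  }
  # cleaned set is dominated by clean cells
  expect_gte(mean(out$matrix$truth$class == "cell"), 0.99)
})

test_that("qc report counts are nonincreasing and reconcile exactly", {
  res <- sim_sample_clean("young", seed = 8, n = 9000)
  qc <- res$qc
  expect_true(all(diff(qc$events_out) <= 0))
  expect_equal(qc$events_in[-1], qc$events_out[-nrow(qc)])
  expect_equal(qc$events_in[1] - qc$events_out[nrow(qc)], sum(qc$removed))
  expect_true(all(qc$fraction_removed >= 0 & qc$fraction_removed <= 1))
})

test_that("cleanup gating is idempotent for fixed parameters", {
  res <- sim_sample_clean("young", seed = 8, n = 9000)
  once <- res$matrix
  twice <- cleanup_gate(once, res$params)
  expect_identical(twice$matrix$values, once$values)
  expect_true(all(twice$qc$removed == 0))
})

test_that("missing instrument channels are reported by name", {
  panel <- tiny_panel(c("p16", "CD45"), c("senescence", "lineage"))
  m <- toy_events(cbind(1:5, 1:5), panel)
  params <- structure(list(bead_min = 3, dna_bounds = c(0, 10),
                           event_length_max = 10, viability_max = 10,
                           cd45_max = 10, lineage_max = 10),
                      class = "senocyto_cleanup_params")
  expect_error(cleanup_gate(m, params), "instrument_bead")
})

test_that("subsampling is seeded, uniform and order-preserving", {
  panel <- tiny_panel(c("a"))
  m <- event_matrix(matrix(1:1000, ncol = 1), panel)
  expect_equal(n_events(subsample_events(m, 0)), 0L)
  s1 <- subsample_events(m, 100, seed = 42)
  s2 <- subsample_events(m, 100, seed = 42)
  expect_identical(s1$values, s2$values)
  expect_false(identical(s1$values,
                         subsample_events(m, 100, seed = 43)$values))
  expect_true(all(diff(s1$values[, 1]) > 0))  # original order kept
  expect_identical(subsample_events(m, 2000)$values, m$values)
})

test_that("seeded per-sample subsampling pools to the exact total", {
  panel <- tiny_panel("a")
  mats <- lapply(1:8, function(i) {
    event_matrix(matrix(rnorm(500, 10), ncol = 1), panel,
                 sample_id = paste0("s", i))
  })
  pooled <- pool_events(mats, n_per_sample = 250, seed = 1)
  expect_equal(n_events(pooled), 8 * 250)
  expect_equal(unname(table(pooled$sample)), rep(250L, 8),
               ignore_attr = TRUE)
})
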