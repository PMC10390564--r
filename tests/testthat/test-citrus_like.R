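# Stratified hierarchy, cluster features, and SAM permutation association.

two_blob_samples <- function(n_samples = 4, n_events = 300, shift = 6,
                             seed = 30) {
  panel <- tiny_panel(c("m1", "m2", "f1"),
                      c("identity", "identity", "sasp"))
  set.seed(seed)
  lapply(seq_len(n_samples), function(i) {
    half <- n_events / 2
    vals <- cbind(
      c(rnorm(half, 0, 0.4), rnorm(half, shift, 0.4)),
      c(rnorm(half, 0, 0.4), rnorm(half, shift, 0.4)),
      rnorm(n_events, 1, 0.2))
    toy_events(vals, panel, sample_id = paste0("s", i))
  })
}

test_that("retained clusters respect the minimum size and nest properly", {
  mats <- two_blob_samples()
  h <- build_hierarchy(mats, n_per_sample = 200, min_fraction = 0.02,
                       channels = c("m1", "m2"), seed = 1)
  expect_equal(h$n_pooled, 800)
  sizes <- vapply(h$members, length, integer(1))
  expect_true(all(sizes >= ceiling(0.02 * 800)))
  # brute-force nesting: any two retained clusters are disjoint or nested
  for (i in seq_along(h$members)) {
    for (j in seq_along(h$members)) {
      if (i >= j) next
      inter <- length(intersect(h$members[[i]], h$members[[j]]))
      expect_true(inter == 0 ||
                    inter == min(length(h$members[[i]]),
                                 length(h$members[[j]])))
    }
  }
  # the root (all events) is retained
  expect_true(any(sizes == 800))
})

test_that("min_fraction near one retains only the root", {
  mats <- two_blob_samples(n_samples = 2, n_events = 100)
  h <- build_hierarchy(mats, n_per_sample = 100, min_fraction = 0.999,
                       channels = c("m1", "m2"), seed = 1)
  expect_equal(length(h$members), 1L)
  expect_equal(length(h$members[[1]]), 200L)
})

test_that("undersized samples are taken whole with a warning", {
  mats <- two_blob_samples(n_samples = 2, n_events = 100)
  expect_warning(h <- build_hierarchy(mats, n_per_sample = 150,
                                      min_fraction = 0.05,
                                      channels = c("m1", "m2"), seed = 1),
                 "smaller than n_per_sample")
  expect_equal(h$n_pooled, 200)
  mats1 <- two_blob_samples(n_samples = 1, n_events = 20)
  expect_error(build_hierarchy(mats1, n_per_sample = 20, min_fraction = 0.01,
                               channels = c("m1", "m2"), seed = 1),
               "below 1/min_fraction")
})

test_that("hierarchy and features are independent of sample order", {
  mats <- two_blob_samples()
  h1 <- build_hierarchy(mats, n_per_sample = 150, min_fraction = 0.05,
                        channels = c("m1", "m2"), seed = 9)
  f1 <- extract_features(h1, "abundance")
  h2 <- build_hierarchy(rev(mats), n_per_sample = 150, min_fraction = 0.05,
                        channels = c("m1", "m2"), seed = 9)
  f2 <- extract_features(h2, "abundance")
  # same per-sample seeded subsample -> same retained cluster sizes and the
  # same abundance feature multiset per sample
  expect_equal(sort(vapply(h1$members, length, integer(1))),
               sort(vapply(h2$members, length, integer(1))))
  for (s in colnames(f1$matrix)) {
    expect_equal(sort(f1$matrix[, s]), sort(f2$matrix[, s]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("features match hand-computed fractions and medians on a toy", {
  panel <- tiny_panel(c("m1", "f1"), c("identity", "sasp"))
  # 6 events, 2 samples; m1 separates {1,2,3} from {10,11,12}
  a <- toy_events(cbind(c(1, 2, 10), c(5, 6, 7)), panel, sample_id = "A")
  b <- toy_events(cbind(c(3, 11, 12), c(1, 2, 3)), panel, sample_id = "B")
  h <- build_hierarchy(list(a, b), n_per_sample = 3, min_fraction = 0.33,
                       channels = "m1", seed = 1)
  ab <- extract_features(h, "abundance")
  # the low blob {1,2,3} holds events A1, A2, B1 -> fractions 2/3 and 1/3
  sizes <- vapply(h$members, length, integer(1))
  low <- which(vapply(seq_along(h$members), function(i) {
    sizes[i] == 3 && all(h$values[h$members[[i]], "m1"] < 5)
  }, logical(1)))
  expect_length(low, 1L)
  expect_equal(ab$matrix[low, "A"], 2 / 3)
  expect_equal(ab$matrix[low, "B"], 1 / 3)
  # root abundance is 1 for every sample
  root <- which(sizes == 6)
  expect_equal(unname(ab$matrix[root, ]), c(1, 1))
  expect_true(all(ab$matrix >= 0 & ab$matrix <= 1))

  md <- suppressWarnings(extract_features(h, "median_marker", "f1"))
  rowid <- paste0("cluster", h$retained[low], "_f1")
  expect_equal(md$matrix[rowid, "A"], median(c(5, 6)))
  expect_equal(md$matrix[rowid, "B"], 1)
  expect_error(extract_features(h, "median_marker", character(0)),
               "non-empty")
})

test_that("the SAM d statistic matches the closed form on one feature", {
  panel_samples <- c("s1", "s2", "s3", "s4", "s5", "s6")
  feat <- structure(list(
    matrix = matrix(c(1, 2, 3, 11, 12, 13), nrow = 1,
                    dimnames = list("f", panel_samples)),
    meta = data.frame(feature = "f", cluster = 1L, marker = NA),
    type = "abundance", samples = panel_samples),
    class = "senocyto_features")
  groups <- stats::setNames(rep(c("a", "b"), each = 3), panel_samples)
  expect_warning(res <- sam_association(feat, groups, n_permutations = 1000,
                                        seed = 1),
                 "fewer distinct")
  ma <- 2; mb <- 12
  sp <- sqrt(((2 * 1 + 2 * 1) / 4) * (1 / 3 + 1 / 3))
  s0 <- sp  # single feature: median pooled SE is itself
  expect_equal(res$results$d, (mb - ma) / (sp + s0))
})

test_that("SAM controls false discoveries on pure-null features", {
  set.seed(33)
  empty_runs <- 0
  n_runs <- 60
  samples <- paste0("s", 1:24)
  groups <- stats::setNames(rep(c("a", "b"), each = 12), samples)
  for (r in seq_len(n_runs)) {
    x <- matrix(rnorm(120 * 24), nrow = 120,
                dimnames = list(paste0("f", 1:120), samples))
    feat <- structure(list(matrix = x,
                           meta = data.frame(feature = rownames(x),
                                             cluster = seq_len(120),
                                             marker = NA),
                           type = "abundance", samples = samples),
                      class = "senocyto_features")
    res <- sam_association(feat, groups, target_fdr = 0.05,
                           n_permutations = 200, seed = r)
    if (sum(res$results$significant) == 0) empty_runs <- empty_runs + 1
  }
  expect_gte(empty_runs / n_runs, 0.95)
})

test_that("SAM recovers planted effects at controlled empirical FDR", {
  set.seed(34)
  samples <- paste0("s", 1:24)
  groups <- stats::setNames(rep(c("a", "b"), each = 12), samples)
  x <- matrix(rnorm(200 * 24), nrow = 200,
              dimnames = list(paste0("f", 1:200), samples))
  planted <- 1:10
  x[planted, 13:24] <- x[planted, 13:24] + 3  # 3-sd shift
  feat <- structure(list(matrix = x,
                         meta = data.frame(feature = rownames(x),
                                           cluster = seq_len(200),
                                           marker = NA),
                         type = "abundance", samples = samples),
                    class = "senocyto_features")
  res <- sam_association(feat, groups, target_fdr = 0.05,
                         n_permutations = 500, seed = 2)
  sig <- which(res$results$significant)
  expect_true(all(planted %in% sig))
  emp_fdr <- length(setdiff(sig, planted)) / max(length(sig), 1)
  expect_lte(emp_fdr, 0.10)
  # q nonincreasing in |d|
  o <- order(abs(res$results$d), decreasing = TRUE)
  expect_true(all(diff(res$results$q[o]) >= -1e-12))
})

test_that("cleared-cluster summaries annotate the depleted population", {
  # samples where group b loses most of the second (CD24-high-like) blob
  panel <- panel_definition(data.frame(
    marker = c("CD24", "Osterix", "Runx2", "f1"),
    metal = c("142Nd", "151Eu", "147Sm", "160Gd"),
    category = c("identity", "identity", "identity", "sasp")))
  gen <- function(id, frac_high, seed) {
    set.seed(seed)
    n <- 240
    nh <- round(n * frac_high)
    vals <- rbind(
      cbind(rnorm(n - nh, 0.2, 0.3), rnorm(n - nh, 0.2, 0.3),
            rnorm(n - nh, 0.2, 0.3), rnorm(n - nh, 1, 0.2)),
      cbind(rnorm(nh, 4.5, 0.35), rnorm(nh, 3.5, 0.35),
            rnorm(nh, 3.5, 0.35), rnorm(nh, 1, 0.2)))
    toy_events(vals, panel, sample_id = id)
  }
  vehicle <- lapply(1:5, function(i) gen(paste0("v", i), 0.30, 100 + i))
  treated <- lapply(1:5, function(i) gen(paste0("t", i), 0.05, 200 + i))
  h <- build_hierarchy(c(vehicle, treated), n_per_sample = 240,
                       min_fraction = 0.03,
                       channels = c("CD24", "Osterix", "Runx2"), seed = 3)
  feats <- extract_features(h, "abundance")
  groups <- stats::setNames(rep(c("vehicle", "treated"), each = 5),
                            vapply(c(vehicle, treated), `[[`, "", "sample_id"))
  assoc <- sam_association(feats, groups, target_fdr = 0.05,
                           n_permutations = 250, seed = 4)
  # restrict the rules to the markers this reduced panel carries
  rules <- load_annotation_rules()
  rules$rules <- Filter(function(r) {
    all(c(r$high, r$low) %in% c("CD24", "Osterix", "Runx2"))
  }, rules$rules)
  rep_tab <- summarize_cleared_clusters(assoc, h, feats, rules)
  expect_equal(nrow(rep_tab), sum(assoc$results$significant))
  dec <- rep_tab[rep_tab$direction == "decreased", ]
  expect_gt(nrow(dec), 0)
  # the depleted clusters are CD24/Osterix/Runx2-high
  expect_true(any(dec$CD24 > 2 & dec$Runx2 > 2))

  none <- assoc
  none$results$significant <- FALSE
  expect_equal(nrow(summarize_cleared_clusters(none, h, feats, rules)), 0L)
})
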