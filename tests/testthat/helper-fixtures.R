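# Shared fixtures: small panels, toy event matrices and cached simulated
# samples. Everything is generated in code; nothing is read from disk except
# the shipped package configs.

tiny_panel <- function(markers = c("p16", "Ki67", "BCL-2"),
                       categories = NULL) {
  n <- length(markers)
  if (is.null(categories)) categories <- rep("senescence", n)
  panel_definition(data.frame(
    marker = markers,
    metal = paste0(100 + seq_len(n), "X"),
    category = categories, stringsAsFactors = FALSE))
}

toy_events <- function(values, panel, transformed = TRUE, ...) {
  event_matrix(as.matrix(values), panel, transformed = transformed, ...)
}

# cache expensive simulations across tests within one run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_env)) {
    assign(key, force(expr), .fixture_env)
  }
  get(key, .fixture_env)
}

# a single mid-size simulated sample with default config, preprocessed
sim_sample_clean <- function(group = "old", seed = 5, n = 12000) {
  key <- paste0("clean_", group, "_", seed, "_", n)
  cached(key, {
    cfg <- default_simulation_config()
    m <- simulate_sample(cfg, group, seed, n_events = n)
    preprocess_sample(m)
  })
}

# adjusted Rand index between two labelings (independent oracle for
# cluster-recovery checks)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}

# spearman rank correlation (small-sample oracle)
spearman <- function(x, y) stats::cor(rank(x), rank(y))
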