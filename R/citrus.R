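# CITRUS-style stratified association analysis: pooled seeded subsampling,
# agglomerative event clustering with a minimum cluster size, per-cluster
# features (abundance or marker medians) per sample, and SAM permutation
# association at a target false discovery rate.

#' Build a stratified cluster hierarchy
#'
#' Subsamples `n_per_sample` events from every sample (all events with a
#' warning when a sample is smaller), pools them, and clusters the pool by
#' average-linkage agglomerative clustering on the clustering channels.
#' Every merge node containing at least `min_fraction` of the pooled events
#' is retained as a (nested, overlapping) cluster; the root is always
#' retained.
#'
#' @param matrices list of transformed `senocyto_events` (one per sample).
#' @param n_per_sample events subsampled per sample.
#' @param min_fraction minimum cluster size as a fraction of the pool.
#' @param channels clustering channels; defaults to the identity markers.
#' @param seed integer seed for the per-sample subsampling.
#' @return A `senocyto_hierarchy`: pooled values, per-event sample ids,
#'   retained cluster member lists, and the linkage object.
#' @export
build_hierarchy <- function(matrices, n_per_sample = 2000,
                            min_fraction = 0.02, channels = NULL,
                            seed = 1L) {
  stopifnot(length(matrices) >= 1, min_fraction > 0, min_fraction < 1)
  if (is.null(channels)) {
    channels <- panel_markers(matrices[[1]]$panel, "identity")
  }
  short <- vapply(matrices, function(m) n_events(m) < n_per_sample, logical(1))
  if (any(short)) {
    warning(sum(short), " sample(s) smaller than n_per_sample; taking all events")
  }
  pooled <- pool_events(matrices, n_per_sample = n_per_sample, seed = seed)
  n <- n_events(pooled)
  if (n < 1 / min_fraction) {
    stop("pooled event count (", n, ") below 1/min_fraction")
  }
  x <- pooled$values[, .marker_col(pooled$panel, channels), drop = FALSE]
  hc <- stats::hclust(stats::dist(x), method = "average")

  # member sets per merge node, bottom-up
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    left <- hc$merge[i, 1]
    right <- hc$merge[i, 2]
    take <- function(j) if (j < 0) -j else members[[j]]
    members[[i]] <- c(take(left), take(right))
  }
  min_size <- ceiling(min_fraction * n)
  retained <- which(vapply(members, length, integer(1)) >= min_size)
  structure(list(
    values = pooled$values, sample_ids = pooled$sample,
    channels = channels, panel = pooled$panel,
    merge = hc$merge, height = hc$height,
    retained = retained, members = members[retained],
    min_fraction = min_fraction, n_pooled = n, seed = seed),
    class = "senocyto_hierarchy")
}

#' @export
print.senocyto_hierarchy <- function(x, ...) {
  cat("senocyto hierarchy: ", x$n_pooled, " pooled events, ",
      length(x$retained), " retained clusters (min ",
      100 * x$min_fraction, "% of pool)\n", sep = "")
  invisible(x)
}

#' Extract per-cluster features per sample
#'
#' `abundance`: the fraction of each sample's subsampled events falling in
#' each retained cluster (nested clusters overlap; fractions do not sum to
#' one). `median_marker`: per-sample median of each functional channel
#' within the cluster; samples without events in a cluster yield `NA` for
#' that feature with a warning.
#'
#' @param h a `senocyto_hierarchy`.
#' @param type `"abundance"` or `"median_marker"`.
#' @param functional_channels markers for `median_marker` features.
#' @return A `senocyto_features`: feature matrix (features x samples) plus
#'   feature metadata (cluster id, marker).
#' @export
extract_features <- function(h, type = c("abundance", "median_marker"),
                             functional_channels = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(h, "senocyto_hierarchy"))
  samples <- unique(h$sample_ids)
  n_clu <- length(h$members)
  per_sample_n <- table(h$sample_ids)[samples]
  if (type == "abundance") {
    feat <- matrix(0, nrow = n_clu, ncol = length(samples),
                   dimnames = list(NULL, samples))
    for (ci in seq_len(n_clu)) {
      tab <- table(h$sample_ids[h$members[[ci]]])
      feat[ci, names(tab)] <- as.numeric(tab)
    }
    feat <- sweep(feat, 2, as.numeric(per_sample_n), "/")
    meta <- data.frame(feature = paste0("cluster", h$retained, "_abundance"),
                       cluster = h$retained, marker = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    if (is.null(functional_channels) || !length(functional_channels)) {
      stop("median_marker features need a non-empty functional channel list")
    }
    cols <- .marker_col(h$panel, functional_channels)
    feat <- matrix(NA_real_, nrow = n_clu * length(cols),
                   ncol = length(samples), dimnames = list(NULL, samples))
    meta <- data.frame(
      feature = character(n_clu * length(cols)),
      cluster = integer(n_clu * length(cols)),
      marker = character(n_clu * length(cols)), stringsAsFactors = FALSE)
    rix <- 0
    any_na <- FALSE
    for (ci in seq_len(n_clu)) {
      mem <- h$members[[ci]]
      sid <- h$sample_ids[mem]
      for (j in seq_along(cols)) {
        rix <- rix + 1
        v <- h$values[mem, cols[j]]
        med <- tapply(v, factor(sid, levels = samples), stats::median)
        feat[rix, ] <- as.numeric(med)
        meta$feature[rix] <- paste0("cluster", h$retained[ci], "_",
                                    functional_channels[j])
        meta$cluster[rix] <- h$retained[ci]
        meta$marker[rix] <- functional_channels[j]
      }
      if (anyNA(feat[(rix - length(cols) + 1):rix, ])) any_na <- TRUE
    }
    if (any_na) {
      warning("some samples contribute no events to some clusters; medians NA")
    }
  }
  rownames(feat) <- meta$feature
  structure(list(matrix = feat, meta = meta, type = type,
                 samples = samples),
            class = "senocyto_features")
}

#' SAM permutation association
#'
#' Per feature, the moderated difference statistic
#' `d = (mean_B - mean_A) / (s_pooled + s0)` with `s0` the median pooled
#' standard error over features. The null distribution comes from seeded
#' group-label permutations (all distinct permutations when fewer exist than
#' requested, with a warning). Each feature's q-value is the estimated false
#' discovery proportion at its `|d|` threshold: the mean over permutations
#' of the number of null `|d*|` exceedances divided by the observed
#' exceedance count, monotonized so q is nonincreasing in `|d|`. (The mean,
#' rather than the median, keeps the estimator conservative at the extreme
#' thresholds, where per-permutation exceedance counts are mostly zero and
#' their median collapses.)
#'
#' @param features a `senocyto_features`.
#' @param groups named group label per sample (two levels), or a cohort
#'   design whose `group` column covers the feature samples.
#' @param target_fdr target false discovery rate.
#' @param n_permutations requested permutations.
#' @param seed integer seed.
#' @return A `senocyto_sam`: per-feature d, q, significance at the target
#'   FDR, and the permutation summary.
#' @export
sam_association <- function(features, groups, target_fdr = 0.05,
                            n_permutations = 1000, seed = 1L) {
  stopifnot(inherits(features, "senocyto_features"))
  if (inherits(groups, "senocyto_design") || is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$sample_id)
  }
  lab <- groups[features$samples]
  if (anyNA(lab)) stop("group labels missing for some samples")
  lev <- unique(lab)
  if (length(lev) != 2) stop("SAM association requires exactly two groups")
  if (min(table(lab)) < 3) stop("each group needs at least 3 samples")

  x <- features$matrix
  keep <- rowSums(is.na(x)) == 0
  if (!all(keep)) {
    warning(sum(!keep), " feature(s) with missing values dropped")
    x <- x[keep, , drop = FALSE]
  }
  n_feat <- nrow(x)
  ia <- which(lab == lev[1])
  ib <- which(lab == lev[2])

  d_stat <- function(idx_b) {
    idx_a <- setdiff(seq_along(lab), idx_b)
    ma <- rowMeans(x[, idx_a, drop = FALSE])
    mb <- rowMeans(x[, idx_b, drop = FALSE])
    va <- apply(x[, idx_a, drop = FALSE], 1, stats::var)
    vb <- apply(x[, idx_b, drop = FALSE], 1, stats::var)
    na <- length(idx_a); nb <- length(idx_b)
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2) *
                 (1 / na + 1 / nb))
    s0 <- stats::median(sp)
    (mb - ma) / (sp + s0)
  }
  d_obs <- d_stat(ib)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  n_samp <- length(lab)
  nb <- length(ib)
  n_distinct <- choose(n_samp, nb)
  if (n_distinct <= n_permutations) {
    warning("fewer distinct permutations (", n_distinct,
            ") than requested; using all")
    perms <- utils::combn(n_samp, nb, simplify = FALSE)
  } else {
    perms <- lapply(seq_len(n_permutations), function(i) {
      sample.int(n_samp, nb)
    })
  }
  null_d <- vapply(perms, function(pb) abs(d_stat(pb)), numeric(n_feat))
  null_d <- matrix(null_d, nrow = n_feat)

  abs_obs <- abs(d_obs)
  ord <- order(abs_obs)  # ascending |d|
  thr <- abs_obs[ord]
  # per-permutation exceedance counts at every observed |d| threshold via
  # sorted search (values are continuous; ties have measure zero)
  v_counts <- vapply(seq_len(ncol(null_d)), function(j) {
    s <- sort(null_d[, j])
    n_feat - findInterval(thr, s)
  }, integer(n_feat))
  v_counts <- matrix(v_counts, nrow = n_feat)
  v_mean <- rowMeans(v_counts)
  r_obs <- n_feat - seq_len(n_feat) + 1  # observed |d| >= threshold
  q_sorted <- pmin(1, v_mean / pmax(r_obs, 1))
  # q-value: minimum estimated FDR over the rejection regions containing the
  # feature (thresholds at or below its |d|) -> nonincreasing in |d|
  q_sorted <- cummin(q_sorted)
  q <- numeric(n_feat)
  q[ord] <- q_sorted

  res <- data.frame(feature = rownames(x), d = d_obs, q = q,
                    significant = q <= target_fdr, stringsAsFactors = FALSE)
  structure(list(results = res, target_fdr = target_fdr,
                 n_permutations = length(perms), seed = seed,
                 groups = lev,
                 null_summary = c(mean_abs_null = mean(null_d),
                                  q95_abs_null = unname(stats::quantile(null_d, 0.95)))),
            class = "senocyto_sam")
}

#' @export
print.senocyto_sam <- function(x, ...) {
  cat("senocyto SAM: ", nrow(x$results), " features, ",
      sum(x$results$significant), " significant at FDR ", x$target_fdr,
      " (", x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

#' Report significant clusters with their defining-marker profiles
#'
#' For every significant feature, reports the direction of change, the
#' cluster's median identity-marker profile, and the nearest population
#' annotation under the rule set.
#'
#' @param assoc a `senocyto_sam` from [sam_association()].
#' @param h the `senocyto_hierarchy` the features came from.
#' @param rules annotation rules ([load_annotation_rules()]); `NULL` skips
#'   annotation.
#' @param features the `senocyto_features` used for the association (for
#'   cluster ids).
#' @return data.frame with one row per significant feature: feature,
#'   cluster, direction, annotation, and the median profile columns.
#' @export
summarize_cleared_clusters <- function(assoc, h, features, rules = NULL) {
  stopifnot(inherits(assoc, "senocyto_sam"), inherits(h, "senocyto_hierarchy"))
  sig <- assoc$results[assoc$results$significant, , drop = FALSE]
  ident <- panel_markers(h$panel, "identity")
  cols <- .marker_col(h$panel, ident)
  if (nrow(sig) == 0) {
    return(data.frame(feature = character(0), cluster = integer(0),
                      direction = character(0), annotation = character(0)))
  }
  refs <- if (!is.null(rules)) {
    pooled <- event_matrix(h$values, h$panel, sample_id = "pooled",
                           transformed = TRUE)
    .rule_references(rules, pooled)
  } else NULL
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    meta_i <- match(sig$feature[i], features$meta$feature)
    clu <- features$meta$cluster[meta_i]
    mem <- h$members[[match(clu, h$retained)]]
    prof <- apply(h$values[mem, cols, drop = FALSE], 2, stats::median)
    names(prof) <- ident
    annotation <- "unlabeled"
    if (!is.null(refs)) {
      for (r in rules$rules) {
        ok <- all(vapply(r$high, function(mk) {
          mk <- .resolve_marker_name(mk)
          prof[[mk]] > refs$refs[[mk]]
        }, logical(1)))
        if (ok && length(r$low)) {
          ok <- all(vapply(r$low, function(mk) {
            mk <- .resolve_marker_name(mk)
            prof[[mk]] <= refs$refs[[mk]]
          }, logical(1)))
        }
        if (ok && !is.null(r$cd24)) {
          v <- prof[["CD24"]]
          ok <- switch(r$cd24,
                       positive = v > refs$refs[["CD24"]],
                       high = v > refs$cd24_split,
                       low = v > refs$refs[["CD24"]] && v <= refs$cd24_split)
        }
        if (ok) { annotation <- r$population; break }
      }
    }
    cbind(data.frame(feature = sig$feature[i], cluster = clu,
                     d = sig$d[i], q = sig$q[i],
                     direction = if (sig$d[i] < 0) "decreased" else "increased",
                     annotation = annotation, stringsAsFactors = FALSE),
          as.data.frame(as.list(prof), check.names = FALSE))
  })
  do.call(rbind, rows)
}
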