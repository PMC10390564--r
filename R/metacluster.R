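# Hierarchical-consensus metaclustering of SOM nodes and rule-based
# annotation of metaclusters to named mesenchymal populations.

#' Consensus metaclustering of SOM nodes
#'
#' For each iteration, a weighted bootstrap of the occupied nodes
#' (probability proportional to node occupancy, 80% of nodes per iteration)
#' is clustered by average-linkage hierarchical clustering of the code
#' vectors and cut at `k`. Pairwise co-assignment frequencies, normalized by
#' co-sampling counts, form the consensus matrix; the final metaclusters cut
#' the average-linkage tree of (1 - consensus) at `k`. Events inherit their
#' node's metacluster. Empty nodes take no part and receive no metacluster.
#'
#' @param model a `senocyto_som`.
#' @param matrix the transformed `senocyto_events` to assign (typically the
#'   training matrix).
#' @param k number of metaclusters.
#' @param iterations consensus iterations.
#' @param seed integer seed for the node resampling.
#' @param min_node_events nodes with fewer mapped events than this take no
#'   part in the consensus (they are typically boundary nodes between
#'   populations); their events inherit the metacluster of the nearest
#'   participating node. Default: 0.1% of the events, at least 2.
#' @param min_cluster_frac minimum fraction of events a metacluster must
#'   hold. The consensus tree is cut progressively deeper until `k`
#'   metaclusters of at least this size exist; undersized cuts (boundary
#'   artifacts) are dissolved into the nearest substantive metacluster.
#' @return A `senocyto_metaclusters`: per-event metacluster ids, per-node
#'   assignment, the consensus matrix, per-metacluster marker medians
#'   (`profiles`), sizes, and an empty annotation slot.
#' @export
consensus_metacluster <- function(model, matrix, k, iterations = 10,
                                  seed = 1L, min_node_events = NULL,
                                  min_cluster_frac = 0.01) {
  stopifnot(inherits(model, "senocyto_som"), k >= 1, iterations >= 1)
  mapping <- map_to_nodes(model, matrix)
  n_nodes <- nrow(model$codes)
  occupancy <- tabulate(mapping, nbins = n_nodes)
  if (is.null(min_node_events)) {
    min_node_events <- max(2, ceiling(0.001 * length(mapping)))
  }
  occupied <- which(occupancy >= min_node_events)
  if (length(occupied) < k) occupied <- which(occupancy > 0)
  n_occ <- length(occupied)
  if (k > n_occ) stop("k (", k, ") exceeds occupied node count (", n_occ, ")")

  node_meta <- rep(NA_integer_, n_nodes)
  if (k == 1L || n_occ == 1L) {
    node_meta[occupied] <- 1L
    consensus <- matrix(1, n_occ, n_occ)
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    })
    set.seed(seed)
    codes <- model$codes[occupied, , drop = FALSE]
    co_cluster <- matrix(0, n_occ, n_occ)
    co_sample <- matrix(0, n_occ, n_occ)
    m <- max(2L, round(0.8 * n_occ))
    for (it in seq_len(iterations)) {
      take <- sample.int(n_occ, m, prob = occupancy[occupied])
      take <- sort(unique(take))
      if (length(take) < 2) next
      hc <- stats::hclust(stats::dist(codes[take, , drop = FALSE]),
                          method = "average")
      lab <- stats::cutree(hc, k = min(k, length(take)))
      ind <- outer(lab, lab, "==") * 1
      co_cluster[take, take] <- co_cluster[take, take] + ind
      co_sample[take, take] <- co_sample[take, take] + 1
    }
    consensus <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
    diag(consensus) <- 1
    consensus <- (consensus + t(consensus)) / 2
    hc_final <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
    # Cut the consensus tree deeper until k substantive metaclusters exist:
    # a metacluster must hold >= min_cluster_frac of the events, otherwise it
    # is a boundary-node artifact and is dissolved into the nearest (by code
    # vector) substantive metacluster.
    min_meta_events <- ceiling(min_cluster_frac * length(mapping))
    node_events <- occupancy[occupied]
    lab_final <- NULL
    for (k_cut in k:n_occ) {
      lab <- stats::cutree(hc_final, k = k_cut)
      meta_sizes <- tapply(node_events, lab, sum)
      big <- as.integer(names(meta_sizes)[meta_sizes >= min_meta_events])
      if (length(big) >= k || k_cut == n_occ) {
        small_nodes <- which(!(lab %in% big))
        if (length(big) && length(small_nodes)) {
          big_nodes <- which(lab %in% big)
          for (nd in small_nodes) {
            d2 <- rowSums((codes[big_nodes, , drop = FALSE] -
                             matrix(codes[nd, ], nrow = length(big_nodes),
                                    ncol = ncol(codes), byrow = TRUE))^2)
            lab[nd] <- lab[big_nodes[which.min(d2)]]
          }
        }
        lab_final <- match(lab, sort(unique(lab)))
        break
      }
    }
    node_meta[occupied] <- lab_final
  }

  # low-occupancy and unassigned nodes inherit the nearest assigned node's
  # metacluster so every event lands in exactly one metacluster
  leftover <- which(is.na(node_meta) & occupancy > 0)
  if (length(leftover)) {
    ref_codes <- model$codes[occupied, , drop = FALSE]
    for (nd in leftover) {
      d2 <- rowSums((ref_codes - matrix(model$codes[nd, ], nrow = n_occ,
                                        ncol = ncol(ref_codes),
                                        byrow = TRUE))^2)
      node_meta[nd] <- node_meta[occupied[which.min(d2)]]
    }
  }

  meta <- node_meta[mapping]
  k_eff <- max(node_meta, na.rm = TRUE)
  profiles <- matrix(NA_real_, nrow = k_eff, ncol = ncol(matrix$values),
                     dimnames = list(NULL, colnames(matrix$values)))
  for (ki in seq_len(k_eff)) {
    rows <- which(meta == ki)
    if (length(rows)) {
      profiles[ki, ] <- apply(matrix$values[rows, , drop = FALSE], 2,
                              stats::median)
    }
  }
  structure(list(
    metacluster = meta, node_assign = node_meta, k = k,
    consensus = consensus, occupied_nodes = occupied,
    profiles = profiles, sizes = tabulate(meta, nbins = k_eff),
    channels = model$channels, annotation = NULL, seed = seed),
    class = "senocyto_metaclusters")
}

#' @export
print.senocyto_metaclusters <- function(x, ...) {
  cat("senocyto metaclusters: k = ", x$k, ", sizes ",
      paste(x$sizes, collapse = "/"), "\n", sep = "")
  if (!is.null(x$annotation)) {
    cat("  labels: ", paste(unique(x$annotation), collapse = ", "), "\n")
  }
  invisible(x)
}

# Exact 1-D two-means split: boundary minimizing within-class sum of squares
# over all sorted split points; returns the midpoint of the two class means.
# Deterministic and order-independent; large vectors are thinned to a
# deterministic grid of order statistics.
.split1d <- function(x, max_n = 20000) {
  x <- sort(x)
  n <- length(x)
  if (n > max_n) x <- x[round(seq(1, n, length.out = max_n))]
  n <- length(x)
  if (n < 2 || x[1] == x[n]) return(x[1])
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  i <- seq_len(n - 1)
  ss_left <- cs2[i] - cs[i]^2 / i
  ss_right <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  best <- which.min(ss_left + ss_right)
  mean_left <- cs[best] / best
  mean_right <- (cs[n] - cs[best]) / (n - best)
  (mean_left + mean_right) / 2
}

#' Load an annotation rule set
#'
#' @param path YAML rule file (see the shipped `config/population_rules.yaml`);
#'   `NULL` loads the shipped population rules.
#' @return A `senocyto_rules` list with `rules` (priority-ordered) and
#'   `reference` method (`"split"` or `"quantile"`).
#' @export
load_annotation_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "config", "population_rules.yaml",
                        package = "senocyto")
  }
  if (!nzchar(path) || !file.exists(path)) stop("rule file not found: ", path)
  raw <- yaml::read_yaml(path)
  rules <- raw$rules
  prio <- vapply(rules, function(r) as.numeric(r$priority), numeric(1))
  if (anyDuplicated(prio)) stop("rule configuration error: duplicate priorities")
  rules <- rules[order(prio)]
  structure(list(rules = rules,
                 reference = if (is.null(raw$reference)) "split" else raw$reference,
                 high_quantile = if (is.null(raw$high_quantile)) 0.6 else raw$high_quantile,
                 low_quantile = if (is.null(raw$low_quantile)) 0.4 else raw$low_quantile),
            class = "senocyto_rules")
}

# Positivity reference levels for the markers a rule set touches, computed
# from the pooled event intensities.
.rule_references <- function(rules, matrix) {
  mks <- unique(unlist(lapply(rules$rules, function(r) c(r$high, r$low))))
  use_cd24 <- any(vapply(rules$rules, function(r) !is.null(r$cd24), logical(1)))
  if (use_cd24) mks <- unique(c(mks, "CD24"))
  unknown <- mks[is.na(.marker_col(matrix$panel, mks, required = FALSE))]
  if (length(unknown)) {
    stop("rule configuration error: unknown marker(s) ",
         paste(unknown, collapse = ", "))
  }
  refs <- vapply(mks, function(mk) {
    x <- .marker_values(matrix, mk)
    if (rules$reference == "quantile") {
      unname(stats::quantile(x, rules$high_quantile, type = 7))
    } else {
      .split1d(x)
    }
  }, numeric(1))
  names(refs) <- .resolve_marker_name(mks)
  cd24_split <- NA_real_
  if (use_cd24) {
    x <- .marker_values(matrix, "CD24")
    pos <- x[x > refs[["CD24"]]]
    cd24_split <- if (length(pos) >= 2) .split1d(pos) else refs[["CD24"]]
  }
  list(refs = refs, cd24_split = cd24_split)
}

#' Annotate metaclusters with population rules
#'
#' Each metacluster is labeled by the highest-priority rule whose
#' required-high markers exceed and required-low markers fall below the
#' positivity references (per-marker two-means splits of the pooled event
#' intensities by default). A rule may additionally constrain CD24 to the
#' `positive`, `low` or `high` band, where the high/low boundary is the
#' two-means split within the CD24-positive subset. Unmatched metaclusters
#' are labeled `"unlabeled"`.
#'
#' @param result a `senocyto_metaclusters` with profiles computed.
#' @param rules a `senocyto_rules`.
#' @param matrix the transformed `senocyto_events` the metaclusters were
#'   computed on (reference levels are cohort-level).
#' @return The `senocyto_metaclusters` with `annotation` (per-metacluster
#'   label) and `event_label` filled in.
#' @export
annotate_clusters <- function(result, rules, matrix) {
  stopifnot(inherits(result, "senocyto_metaclusters"),
            inherits(rules, "senocyto_rules"))
  rr <- .rule_references(rules, matrix)
  refs <- rr$refs
  profiles <- result$profiles
  labels <- rep("unlabeled", nrow(profiles))
  for (ki in seq_len(nrow(profiles))) {
    prof <- profiles[ki, ]
    if (anyNA(prof[1])) next
    for (r in rules$rules) {
      ok <- TRUE
      for (mk in r$high) {
        mk <- .resolve_marker_name(mk)
        if (!(prof[[mk]] > refs[[mk]])) { ok <- FALSE; break }
      }
      if (ok) for (mk in r$low) {
        mk <- .resolve_marker_name(mk)
        if (!(prof[[mk]] <= refs[[mk]])) { ok <- FALSE; break }
      }
      if (ok && !is.null(r$cd24)) {
        v <- prof[["CD24"]]
        ok <- switch(r$cd24,
                     positive = v > refs[["CD24"]],
                     high = v > rr$cd24_split,
                     low = v > refs[["CD24"]] && v <= rr$cd24_split,
                     stop("rule configuration error: cd24 band must be positive/low/high"))
      }
      if (ok) { labels[ki] <- r$population; break }
    }
  }
  result$annotation <- labels
  result$event_label <- labels[result$metacluster]
  result
}

#' Silhouette-based choice of the metacluster count
#'
#' Runs consensus metaclustering for each candidate `k` and scores the mean
#' silhouette width of the events (subsampled for scoring) on the clustering
#' channels; returns the `k` maximizing it together with the full
#' silhouette-versus-k table. A maximum below 0.4 (at best weak structure on
#' the Kaufman-Rousseeuw silhouette scale) raises the `no_structure` flag.
#'
#' @param model a `senocyto_som`.
#' @param matrix transformed `senocyto_events`.
#' @param k_range integer candidates (within `[2, occupied nodes]`).
#' @param iterations consensus iterations per candidate.
#' @param seed integer seed.
#' @param score_events events used for silhouette scoring (subsampled
#'   without replacement).
#' @return List with `k` (chosen), `table` (k, mean silhouette),
#'   `no_structure` flag.
#' @export
select_k <- function(model, matrix, k_range = 2:10, iterations = 10,
                     seed = 1L, score_events = 4000) {
  stopifnot(inherits(model, "senocyto_som"))
  x <- matrix$values[, .marker_col(matrix$panel, model$channels), drop = FALSE]
  if (all(apply(x, 2, function(col) max(col) - min(col)) < 1e-12)) {
    stop("degenerate input: all events identical on the clustering channels")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  n <- nrow(x)
  idx <- if (n > score_events) sort(sample.int(n, score_events)) else seq_len(n)
  dmat <- stats::dist(x[idx, , drop = FALSE])
  sil <- vapply(k_range, function(k) {
    mc <- consensus_metacluster(model, matrix, k = k, iterations = iterations,
                                seed = seed)
    lab <- mc$metacluster[idx]
    if (length(unique(lab)) < 2) return(NA_real_)
    mean(cluster::silhouette(lab, dmat)[, "sil_width"])
  }, numeric(1))
  tab <- data.frame(k = k_range, silhouette = sil)
  best <- k_range[which.max(sil)]
  list(k = best, table = tab,
       no_structure = all(is.na(sil)) || max(sil, na.rm = TRUE) < 0.4)
}

#' Per-sample metacluster abundance fractions
#'
#' @param result a `senocyto_metaclusters` computed on pooled events.
#' @param sample_ids per-event sample ids (e.g. the `sample` element of
#'   [pool_events()] output).
#' @return data.frame sample_id x cluster with columns `sample_id`,
#'   `cluster`, `label` (if annotated), `fraction`.
#' @export
cluster_abundance <- function(result, sample_ids) {
  stopifnot(length(sample_ids) == length(result$metacluster))
  tab <- table(sample_ids, result$metacluster)
  frac <- sweep(tab, 1, rowSums(tab), "/")
  out <- as.data.frame(frac, stringsAsFactors = FALSE)
  names(out) <- c("sample_id", "cluster", "fraction")
  out$cluster <- as.integer(as.character(out$cluster))
  if (!is.null(result$annotation)) {
    out$label <- result$annotation[out$cluster]
  }
  out[order(out$sample_id, out$cluster), ]
}
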