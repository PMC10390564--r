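# Subpopulation profiling: boolean gate expressions over marker calls and
# cluster labels, senescence-marker enrichment profiles, per-cluster
# senescent burden, and senolytic clearance reports.

# --- minimal boolean gate grammar -------------------------------------------
# expr    := term ('OR' term)*
# term    := factor ('AND' factor)*
# factor  := 'NOT' factor | '(' expr ')' | ident
# ident   := flag name (e.g. p16, p16KB) or cluster:"Label"
# Tokens are case-sensitive for flag names; AND/OR/NOT are keywords.

.gate_tokens <- function(expr) {
  pat <- "cluster:\"[^\"]*\"|\\(|\\)|[A-Za-z0-9_+/.-]+"
  m <- gregexpr(pat, expr)[[1]]
  if (m[1] == -1) stop("gate parse error at position 1: empty expression")
  toks <- regmatches(expr, gregexpr(pat, expr))[[1]]
  # verify nothing but whitespace was skipped
  consumed <- gsub(pat, "", expr)
  if (grepl("[^ \t]", consumed)) {
    bad <- regmatches(consumed, regexpr("[^ \t]", consumed))
    stop("gate parse error: unexpected character '", bad, "' in \"", expr, "\"")
  }
  data.frame(token = toks, pos = as.integer(m), stringsAsFactors = FALSE)
}

#' Parse a gate expression
#'
#' Boolean grammar over named per-event flags and cluster labels:
#' `AND`, `OR`, `NOT`, parentheses, flag names (e.g. `p16`, `p16KB`) and
#' `cluster:"Label"` atoms. Returns an evaluator that maps an environment
#' (list with logical flag vectors and optionally `cluster_label`) to a
#' logical event mask.
#'
#' @param expr gate expression string, e.g. `"p16 AND NOT Ki67 AND BCL-2"`.
#' @return Function `(env) -> logical vector`.
#' @export
parse_gate <- function(expr) {
  toks <- .gate_tokens(expr)
  i <- 1L
  peek <- function() if (i <= nrow(toks)) toks$token[i] else NA_character_
  advance <- function() { t <- toks$token[i]; i <<- i + 1L; t }
  fail <- function(msg) {
    pos <- if (i <= nrow(toks)) toks$pos[i] else nchar(expr) + 1L
    stop("gate parse error at position ", pos, ": ", msg)
  }
  # combinators bind operands in a fresh environment per application
  or_node <- function(lhs, rhs) {
    force(lhs); force(rhs)
    function(env) lhs(env) | rhs(env)
  }
  and_node <- function(lhs, rhs) {
    force(lhs); force(rhs)
    function(env) lhs(env) & rhs(env)
  }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && peek() == "OR") {
      advance()
      node <- or_node(node, parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && peek() == "AND") {
      advance()
      node <- and_node(node, parse_factor())
    }
    node
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of expression")
    if (t == "NOT") {
      advance()
      inner <- parse_factor()
      return(function(env) !inner(env))
    }
    if (t == "(") {
      advance()
      inner <- parse_expr()
      if (is.na(peek()) || peek() != ")") fail("expected ')'")
      advance()
      return(inner)
    }
    if (t == ")" || t == "AND" || t == "OR") fail(paste0("unexpected '", t, "'"))
    advance()
    if (startsWith(t, "cluster:")) {
      label <- sub("^cluster:\"(.*)\"$", "\\1", t)
      return(function(env) {
        if (is.null(env$cluster_label)) {
          stop("gate references cluster labels but none supplied")
        }
        env$cluster_label == label
      })
    }
    function(env) {
      v <- env[[t]]
      if (is.null(v)) stop("gate references undefined flag '", t, "'")
      v
    }
  }
  root <- parse_expr()
  if (!is.na(peek())) fail(paste0("trailing input '", peek(), "'"))
  root
}

# Evaluate a gate over one sample's calls (+ optional cluster labels).
.eval_gate <- function(gate, calls, cluster_label = NULL) {
  env <- as.list(calls$flags)
  env$cluster_label <- cluster_label
  if (is.character(gate)) gate <- parse_gate(gate)
  gate(env)
}

#' Profile a gated subset
#'
#' Per-sample mean expression and percent-positive for the requested markers
#' within the events selected by a boolean gate expression. Samples whose
#' subset is empty are excluded with a warning.
#'
#' @param matrices one `senocyto_events` or a list (cleaned, transformed).
#' @param calls matching `senocyto_calls` (same order).
#' @param subset gate expression string or parsed gate.
#' @param markers markers to profile.
#' @param cluster_labels optional per-sample list of per-event cluster
#'   labels (for `cluster:"..."` atoms).
#' @return data.frame: sample_id, n_subset, then `mean_<marker>` and (when
#'   the marker is among the called flags) `pctpos_<marker>` columns.
#' @export
profile_subset <- function(matrices, calls, subset, markers,
                           cluster_labels = NULL) {
  if (inherits(matrices, "senocyto_events")) {
    matrices <- list(matrices)
    calls <- list(calls)
  }
  gate <- if (is.character(subset)) parse_gate(subset) else subset
  rows <- list()
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    cl <- calls[[i]]
    sel <- .eval_gate(gate, cl,
                      if (!is.null(cluster_labels)) cluster_labels[[i]])
    if (!any(sel)) {
      warning("subset empty for sample ", m$sample_id, "; excluded")
      next
    }
    row <- list(sample_id = m$sample_id, n_subset = sum(sel))
    for (mk in markers) {
      mkr <- .resolve_marker_name(mk)
      v <- .marker_values(m, mk)[sel]
      row[[paste0("mean_", mkr)]] <- mean(v)
      if (mkr %in% names(cl$flags)) {
        row[[paste0("pctpos_", mkr)]] <- 100 * sum(cl$flags[[mkr]][sel]) / sum(sel)
      }
    }
    rows[[length(rows) + 1]] <- as.data.frame(row, check.names = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(sample_id = character(0), n_subset = integer(0)))
  }
  do.call(rbind, rows)
}

#' Per-cluster senescent burden
#'
#' For pooled, metaclustered events with matching marker calls: per cluster
#' and sample, the percentage of p16KB cells and the mean p16 and BCL-2
#' expression; plus per-cluster group contrasts (routed test, Holm-Sidak
#' within the contrast family).
#'
#' @param pooled pooled `senocyto_events` (from [pool_events()], with
#'   per-event `sample`).
#' @param calls `senocyto_calls` computed on the pooled events.
#' @param metaclusters a `senocyto_metaclusters` on the pooled events.
#' @param design cohort design.
#' @param reference,comparison groups contrasted (default old vs young).
#' @return List with `burden` (cluster x sample metrics) and `contrasts`
#'   (per-cluster log2FC of %p16KB with p values).
#' @export
cluster_burden <- function(pooled, calls, metaclusters, design,
                           reference = "young", comparison = "old") {
  stopifnot(!is.null(pooled$sample))
  meta <- metaclusters$metacluster
  sid <- pooled$sample
  f <- calls$flags
  p16v <- .marker_values(pooled, "p16")
  bclv <- .marker_values(pooled, "BCL-2")
  k_eff <- max(meta, na.rm = TRUE)
  rows <- list()
  for (ki in seq_len(k_eff)) {
    in_k <- meta == ki
    for (s in unique(sid)) {
      sel <- in_k & sid == s
      n <- sum(sel)
      if (n == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        cluster = ki,
        label = if (!is.null(metaclusters$annotation))
          metaclusters$annotation[ki] else NA_character_,
        sample_id = s, n = n,
        pct_p16kb = if ("p16KB" %in% names(f)) 100 * sum(f$p16KB[sel]) / n else NA_real_,
        mean_p16 = mean(p16v[sel]), mean_bcl2 = mean(bclv[sel]),
        stringsAsFactors = FALSE)
    }
  }
  burden <- do.call(rbind, rows)
  burden$group <- design$group[match(burden$sample_id, design$sample_id)]

  contrasts <- list()
  for (ki in seq_len(k_eff)) {
    sub <- burden[burden$cluster == ki, , drop = FALSE]
    a <- sub$pct_p16kb[sub$group == reference]
    b <- sub$pct_p16kb[sub$group == comparison]
    if (length(a) < 2 || length(b) < 2) next
    cmp <- suppressWarnings(compare_groups(a, b, unit = "pct_p16kb"))
    cmp$cluster <- ki
    cmp$label <- sub$label[1]
    contrasts[[length(contrasts) + 1]] <- cmp
  }
  contrasts <- do.call(rbind, contrasts)
  if (!is.null(contrasts) && nrow(contrasts) > 0) {
    contrasts$p_adjusted <- holm_sidak(contrasts$p_raw)$p_adjusted
  }
  list(burden = burden, contrasts = contrasts)
}

#' Senolytic clearance report
#'
#' Per-cluster abundance contrast between two arms with the routed test and
#' Holm-Sidak correction; clusters are labeled `cleared` (adjusted p < 0.05
#' and log2FC at most `-clearance_lfc`), `increased` (adjusted p < 0.05 and
#' log2FC at least `clearance_lfc`), or `unchanged`.
#'
#' @param abundance per-sample cluster abundance data.frame from
#'   [cluster_abundance()].
#' @param design cohort design.
#' @param reference,comparison contrasted arms (vehicle vs treated).
#' @param clearance_lfc absolute log2 fold-change required to call a change.
#' @return data.frame: cluster, label, log2FC, p, adjusted p, direction.
#' @export
clearance_report <- function(abundance, design, reference = "old",
                             comparison = "old_senolytic",
                             clearance_lfc = 0.5) {
  abundance$group <- design$group[match(abundance$sample_id,
                                        design$sample_id)]
  arms <- abundance[abundance$group %in% c(reference, comparison), ,
                    drop = FALSE]
  small <- any(table(unique(arms[, c("sample_id", "group")])$group) < 3)
  if (small) {
    warning("an arm has fewer than 3 samples; forcing nonparametric tests")
  }
  rows <- list()
  for (ki in sort(unique(arms$cluster))) {
    sub <- arms[arms$cluster == ki, , drop = FALSE]
    a <- sub$fraction[sub$group == reference]
    b <- sub$fraction[sub$group == comparison]
    if (!length(a) || !length(b)) next
    test <- if (small) "mann_whitney" else NULL
    cmp <- suppressWarnings(compare_groups(a, b, unit = "abundance",
                                           test = test))
    cmp$cluster <- ki
    cmp$label <- if ("label" %in% names(sub)) sub$label[1] else NA_character_
    rows[[length(rows) + 1]] <- cmp
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_sidak(out$p_raw)$p_adjusted
  out$direction <- ifelse(
    out$p_adjusted < 0.05 & !is.na(out$log2_fold_change) &
      out$log2_fold_change <= -clearance_lfc, "cleared",
    ifelse(out$p_adjusted < 0.05 & !is.na(out$log2_fold_change) &
             out$log2_fold_change >= clearance_lfc, "increased", "unchanged"))
  out
}
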