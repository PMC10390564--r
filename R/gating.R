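# Marker-positivity thresholds and combinatorial senescence calls.
#
# p16 positivity is anchored on a knock-out negative control: the cutoff is
# a high empirical quantile of the control's p16 channel, so the false
# positive rate on true negatives is ~(1 - quantile). Markers without a
# knock-out control are cut at a configured quantile of the pooled young
# cohort. Calls use strict inequality (>), so control events at the cutoff
# are negative. The combinatorial classes are
#   p16KB = p16+ & Ki67- & BCL-2+     and     p21KB = p21+ & Ki67- & BCL-2+.

#' Derive a threshold from a negative-control sample
#'
#' Empirical quantile (linear-interpolation definition, `stats::quantile`
#' type 7) of the control's marker channel on the arcsinh scale.
#'
#' @param control cleaned, transformed `senocyto_events` from the
#'   knock-out (or otherwise marker-negative) control.
#' @param marker marker name.
#' @param quantile quantile in (0, 1); default caps the false-positive rate
#'   at ~0.1%.
#' @return A threshold entry: list with `marker`, `cutoff`, `source`,
#'   `control_sample_id`, `quantile`.
#' @export
derive_threshold <- function(control, marker, quantile = 0.999) {
  stopifnot(inherits(control, "senocyto_events"),
            quantile > 0, quantile < 1)
  if (!control$transformed) stop("control must be arcsinh-transformed")
  if (n_events(control) == 0) stop("control sample is empty")
  x <- .marker_values(control, marker)
  list(marker = .resolve_marker_name(marker),
       cutoff = unname(stats::quantile(x, quantile, type = 7)),
       source = "ko_control",
       control_sample_id = control$sample_id,
       quantile = quantile)
}

#' Derive a threshold from pooled cohort events
#'
#' Cutoff at a configured quantile of the pooled (typically young-cohort)
#' marker distribution; used for markers lacking a knock-out control. The
#' quantile should be placed at the expected negative-fraction boundary so
#' the cutoff falls in the trough between the negative and positive modes.
#'
#' @param matrices list of cleaned, transformed `senocyto_events` to pool.
#' @param marker marker name.
#' @param quantile quantile in (0, 1).
#' @return A threshold entry (source `quantile_of_pooled`).
#' @export
derive_pooled_threshold <- function(matrices, marker, quantile) {
  if (inherits(matrices, "senocyto_events")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1, quantile > 0, quantile < 1)
  x <- unlist(lapply(matrices, function(m) {
    if (!m$transformed) stop("pooled thresholding expects transformed data")
    .marker_values(m, marker)
  }), use.names = FALSE)
  if (length(x) == 0) stop("no events available for pooled threshold")
  list(marker = .resolve_marker_name(marker),
       cutoff = unname(stats::quantile(x, quantile, type = 7)),
       source = "quantile_of_pooled",
       control_sample_id = NULL,
       quantile = quantile)
}

#' Bundle threshold entries into a threshold set
#'
#' @param ... threshold entries from [derive_threshold()],
#'   [derive_pooled_threshold()], or manual entries
#'   (`list(marker=, cutoff=, source="manual")`).
#' @return A `senocyto_thresholds` named list.
#' @export
threshold_set <- function(...) {
  entries <- list(...)
  if (length(entries) == 1 && is.null(entries[[1]]$marker)) {
    entries <- entries[[1]]
  }
  out <- list()
  for (e in entries) {
    stopifnot(!is.null(e$marker), is.finite(e$cutoff))
    if (identical(e$source, "ko_control") && is.null(e$control_sample_id)) {
      stop("ko_control threshold requires control_sample_id")
    }
    out[[e$marker]] <- e
  }
  structure(out, class = "senocyto_thresholds")
}

#' Write / read a threshold set (YAML, with provenance)
#'
#' @param thresholds a `senocyto_thresholds`.
#' @param path YAML file path.
#' @return `path` (write) or the threshold set (read).
#' @export
write_thresholds <- function(thresholds, path) {
  yaml::write_yaml(lapply(unclass(thresholds), function(e) {
    e$cutoff <- as.numeric(e$cutoff)
    e
  }), path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  threshold_set(yaml::read_yaml(path))
}

#' Call per-event marker positivity and senescence classes
#'
#' Positivity is strict: intensity > cutoff. When thresholds for p16 (or
#' p21), Ki67 and BCL-2 are all present, the derived classes p16KB (p21KB)
#' are computed as marker-positive, Ki67-negative, BCL-2-positive.
#'
#' @param matrix cleaned, transformed `senocyto_events`.
#' @param thresholds a `senocyto_thresholds` covering the markers to gate.
#' @param markers markers to call; defaults to all thresholded markers.
#' @return A `senocyto_calls`: list with `flags` (logical data.frame, one
#'   column per marker plus `p16KB`/`p21KB` when derivable) and `sample_id`.
#' @export
call_markers <- function(matrix, thresholds, markers = names(thresholds)) {
  stopifnot(inherits(matrix, "senocyto_events"),
            inherits(thresholds, "senocyto_thresholds"))
  if (!matrix$transformed) stop("call_markers expects transformed data")
  missing_thr <- setdiff(.resolve_marker_name(markers), names(thresholds))
  if (length(missing_thr)) {
    stop("no threshold for marker(s): ", paste(missing_thr, collapse = ", "))
  }
  flags <- as.data.frame(lapply(markers, function(mk) {
    .marker_values(matrix, mk) > thresholds[[.resolve_marker_name(mk)]]$cutoff
  }), col.names = .resolve_marker_name(markers), check.names = FALSE,
  optional = TRUE)
  if (nrow(flags) == 0 && n_events(matrix) == 0) {
    flags <- as.data.frame(matrix(logical(0), nrow = 0,
                                  ncol = length(markers),
                                  dimnames = list(NULL, .resolve_marker_name(markers))))
  }
  has <- function(mk) mk %in% names(flags)
  if (has("p16") && has("Ki67") && has("BCL-2")) {
    flags[["p16KB"]] <- flags[["p16"]] & !flags[["Ki67"]] & flags[["BCL-2"]]
  }
  if (has("p21") && has("Ki67") && has("BCL-2")) {
    flags[["p21KB"]] <- flags[["p21"]] & !flags[["Ki67"]] & flags[["BCL-2"]]
  }
  structure(list(flags = flags, sample_id = matrix$sample_id,
                 n = n_events(matrix)),
            class = "senocyto_calls")
}

#' Per-sample senescence call summary
#'
#' Percentages of clean (cleaned Lin-CD45-) cells that are p16+, p21+,
#' p16KB and p21KB; subset shares (%p16KB of p16+, %Ki67- of p16+BCL-2+);
#' and, when event matrices are supplied, mean arcsinh BCL-2 within the
#' p16+ subset. Undefined shares (empty parent gate) are `NA` and excluded
#' from group summaries with a warning.
#'
#' @param calls list of `senocyto_calls`, one per sample.
#' @param design cohort design; `ko_control` samples are excluded from the
#'   group summary.
#' @param matrices optional list of the matching cleaned `senocyto_events`
#'   (same order), used for subset mean expression.
#' @return List with `samples` (per-sample data.frame) and `groups`
#'   (mean/sd/n per group and metric).
#' @export
summarize_calls <- function(calls, design = NULL, matrices = NULL) {
  if (inherits(calls, "senocyto_calls")) calls <- list(calls)
  stopifnot(length(calls) >= 1)
  rows <- lapply(seq_along(calls), function(i) {
    cl <- calls[[i]]
    f <- cl$flags
    n <- nrow(f)
    pct <- function(col) {
      if (!col %in% names(f) || n == 0) return(NA_real_)
      100 * sum(f[[col]]) / n
    }
    share <- function(num, den) {
      if (!all(c(num, den) %in% names(f))) return(NA_real_)
      d <- sum(f[[den]])
      if (d == 0) return(NA_real_)
      100 * sum(f[[num]] & f[[den]]) / d
    }
    ki67neg_of_p16bcl2 <- if (all(c("p16", "BCL-2", "Ki67") %in% names(f))) {
      parent <- f[["p16"]] & f[["BCL-2"]]
      if (sum(parent) == 0) NA_real_ else 100 * sum(parent & !f[["Ki67"]]) / sum(parent)
    } else NA_real_
    mean_bcl2_p16 <- if (!is.null(matrices) && "p16" %in% names(f) &&
                         sum(f[["p16"]]) > 0) {
      mean(.marker_values(matrices[[i]], "BCL-2")[f[["p16"]]])
    } else NA_real_
    data.frame(
      sample_id = cl$sample_id, n_clean = n,
      pct_p16 = pct("p16"), pct_p21 = pct("p21"),
      pct_p16kb = pct("p16KB"), pct_p21kb = pct("p21KB"),
      share_p16kb_of_p16 = share("p16KB", "p16"),
      pct_ki67neg_of_p16bcl2 = ki67neg_of_p16bcl2,
      mean_bcl2_in_p16 = mean_bcl2_p16,
      stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, rows)
  if (!is.null(design)) {
    samples$group <- design$group[match(samples$sample_id, design$sample_id)]
  } else {
    samples$group <- "all"
  }
  metrics <- c("pct_p16", "pct_p21", "pct_p16kb", "pct_p21kb",
               "share_p16kb_of_p16", "pct_ki67neg_of_p16bcl2",
               "mean_bcl2_in_p16")
  keep <- samples$group != "ko_control" & !is.na(samples$group)
  grp_rows <- list()
  for (g in unique(samples$group[keep])) {
    sub <- samples[keep & samples$group == g, , drop = FALSE]
    for (mt in metrics) {
      v <- sub[[mt]]
      if (any(is.na(v)) && !all(is.na(v))) {
        warning("metric ", mt, " undefined for some samples in group ", g,
                "; excluded from the group summary")
      }
      v <- v[!is.na(v)]
      grp_rows[[length(grp_rows) + 1]] <- data.frame(
        group = g, metric = mt,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  list(samples = samples, groups = do.call(rbind, grp_rows))
}

#' Group fold change of a summary metric
#'
#' Ratio of group means (comparison over reference) with the log2 variant.
#' A zero reference mean yields `NA` fold and `Inf` log2 with a warning.
#'
#' @param summary result of [summarize_calls()] (or its `samples` element).
#' @param metric metric column name.
#' @param reference,comparison group labels.
#' @return List with `fold`, `log2_fold`, and the two group means.
#' @export
group_fold_change <- function(summary, metric, reference, comparison) {
  samples <- if (is.data.frame(summary)) summary else summary$samples
  stopifnot(metric %in% names(samples))
  val <- function(g) {
    v <- samples[[metric]][samples$group == g]
    v <- v[!is.na(v)]
    if (!length(v)) stop("no defined values for group ", g)
    mean(v)
  }
  ref <- val(reference)
  cmp <- val(comparison)
  if (ref == 0) {
    warning("reference mean is zero; fold change undefined")
    return(list(fold = NA_real_, log2_fold = Inf,
                mean_reference = ref, mean_comparison = cmp))
  }
  list(fold = cmp / ref, log2_fold = log2(cmp / ref),
       mean_reference = ref, mean_comparison = cmp)
}
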