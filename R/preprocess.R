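# Preprocessing: bead-anchored drift normalization, arcsinh transform, and
# sequential cleanup gating to the Lin-CD45- mesenchymal analysis set.

#' Bead-anchored drift normalization
#'
#' Corrects slow intra-file signal drift against the spiked calibration
#' beads. Events are split into `n_bins` contiguous acquisition-order bins;
#' each bin's multiplicative correction is the ratio of the global median
#' bead signal to the bin median bead signal (averaged over bead channels,
#' bead events only), clamped to `[0.2, 5]`, and applied to every metal
#' channel of every event in the bin. Event count and order are preserved.
#'
#' @param matrix raw-scale `senocyto_events`.
#' @param panel panel (defaults to the matrix's own panel).
#' @param n_bins number of acquisition bins.
#' @param bead_min_raw raw bead-channel intensity above which an event is
#'   treated as a bead for the purpose of drift estimation.
#' @return Corrected `senocyto_events`.
#' @export
bead_normalize <- function(matrix, panel = matrix$panel, n_bins = 20,
                           bead_min_raw = 50) {
  stopifnot(inherits(matrix, "senocyto_events"))
  if (matrix$transformed) stop("bead_normalize expects raw-scale data")
  bead_cols <- .instrument_col(panel, "instrument_bead")
  el_col <- .instrument_col(panel, "instrument_event_length", required = FALSE)
  n <- n_events(matrix)
  bead_sig <- matrix$values[, bead_cols, drop = FALSE]
  is_bead <- rowSums(bead_sig > bead_min_raw) > 0
  if (sum(is_bead) < n_bins) {
    warning("fewer bead events (", sum(is_bead), ") than bins (", n_bins,
            "); returning input unchanged")
    return(matrix)
  }
  bins <- ceiling(seq_len(n) / (n / n_bins))
  bins[bins > n_bins] <- n_bins
  metal_cols <- setdiff(seq_len(ncol(matrix$values)), el_col)

  # per-bead-channel: global and per-bin medians over bead events
  corr <- rep(1, n_bins)
  per_channel <- sapply(seq_along(bead_cols), function(j) {
    sig <- bead_sig[is_bead, j]
    global_med <- stats::median(sig)
    bin_med <- tapply(sig, bins[is_bead], stats::median)
    out <- rep(NA_real_, n_bins)
    out[as.integer(names(bin_med))] <- global_med / bin_med
    out
  })
  per_channel <- matrix(per_channel, nrow = n_bins)
  corr <- rowMeans(per_channel, na.rm = TRUE)
  corr[!is.finite(corr)] <- 1
  clamped <- corr < 0.2 | corr > 5
  if (any(clamped)) {
    warning(sum(clamped), " bin correction(s) clamped to [0.2, 5]")
    corr <- pmin(pmax(corr, 0.2), 5)
  }
  matrix$values[, metal_cols] <- matrix$values[, metal_cols] * corr[bins]
  matrix
}

#' Arcsinh transform
#'
#' Applies `x -> asinh(x / cofactor)` to every channel. May be applied at
#' most once; the matrix records its scale.
#'
#' @param matrix raw-scale `senocyto_events`.
#' @param cofactor positive scaling cofactor (mass-cytometry convention: 5).
#' @return Transformed `senocyto_events` with `transformed = TRUE`.
#' @export
arcsinh_transform <- function(matrix, cofactor = 5) {
  stopifnot(inherits(matrix, "senocyto_events"), cofactor > 0)
  if (matrix$transformed) stop("matrix is already arcsinh-transformed")
  matrix$values <- asinh(matrix$values / cofactor)
  matrix$transformed <- TRUE
  matrix
}

#' Cleanup gating parameters
#'
#' Data-driven default cutoffs on the arcsinh scale. The bead cutoff is
#' fixed; the remaining cutoffs are robust location/scale estimates
#' (median +/- `k` * MAD) of the non-bead event distributions, so they track
#' whatever intensity scale the acquisition produced: the singlet DNA window,
#' the event-length ceiling, the viability (dead-cell) ceiling and the
#' CD45/lineage negative-selection ceilings.
#'
#' @param matrix transformed `senocyto_events`.
#' @param panel panel.
#' @param bead_min arcsinh bead-channel positivity cutoff.
#' @param k robust-width multiplier.
#' @return A `senocyto_cleanup_params` list.
#' @export
default_cleanup_params <- function(matrix, panel = matrix$panel,
                                   bead_min = 3.0, k = 4) {
  stopifnot(inherits(matrix, "senocyto_events"))
  if (!matrix$transformed) stop("cleanup parameters are derived on arcsinh scale")
  bead_cols <- .instrument_col(panel, "instrument_bead")
  keep <- rowSums(matrix$values[, bead_cols, drop = FALSE] > bead_min) == 0
  v <- matrix$values[keep, , drop = FALSE]
  robust_hi <- function(x) stats::median(x) + k * stats::mad(x)
  dna <- v[, .instrument_col(panel, "instrument_dna")]
  el <- v[, .instrument_col(panel, "instrument_event_length")]
  via <- v[, .instrument_col(panel, "instrument_viability")]
  cd45 <- v[, .marker_col(panel, "CD45")]
  lin_cols <- setdiff(which(panel$channels$category == "lineage"),
                      .marker_col(panel, "CD45"))
  lin_max <- if (length(lin_cols)) {
    max(vapply(lin_cols, function(cc) robust_hi(v[, cc]), numeric(1)))
  } else Inf
  params <- list(
    bead_min = bead_min,
    dna_bounds = c(stats::median(dna) - k * stats::mad(dna),
                   stats::median(dna) + k * stats::mad(dna)),
    event_length_max = robust_hi(el),
    viability_max = robust_hi(via),
    cd45_max = robust_hi(cd45),
    lineage_max = lin_max
  )
  class(params) <- c("senocyto_cleanup_params", "list")
  params
}

#' Sequential cleanup gating
#'
#' Fixed gate order: (1) remove calibration beads (bead channel above
#' `bead_min`); (2) keep singlet cells (DNA inside `dna_bounds` and event
#' length at most `event_length_max`), removing doublets and debris;
#' (3) remove dead cells (viability above `viability_max`); (4) negative
#' selection of the Lin-CD45- compartment (CD45 at most `cd45_max` and all
#' lineage channels at most `lineage_max`). Per-stage event counts and
#' removal fractions are returned as a QC report.
#'
#' @param matrix transformed `senocyto_events`.
#' @param params a `senocyto_cleanup_params` (see
#'   [default_cleanup_params()]).
#' @param panel panel.
#' @return List with elements `matrix` (cleaned events) and `qc`
#'   (data.frame: stage, events_in, events_out, removed, fraction_removed).
#' @export
cleanup_gate <- function(matrix, params, panel = matrix$panel) {
  stopifnot(inherits(matrix, "senocyto_events"))
  if (!matrix$transformed) stop("cleanup_gate expects arcsinh-transformed data")
  stages <- list()
  record <- function(stage, n_in, n_out) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = stage, events_in = n_in, events_out = n_out,
      removed = n_in - n_out,
      fraction_removed = if (n_in > 0) (n_in - n_out) / n_in else 0,
      stringsAsFactors = FALSE)
  }
  m <- matrix

  bead_cols <- .instrument_col(panel, "instrument_bead")
  n_in <- n_events(m)
  keep <- rowSums(m$values[, bead_cols, drop = FALSE] > params$bead_min) == 0
  m <- .subset_events(m, keep)
  record("bead_removal", n_in, n_events(m))

  dna_col <- .instrument_col(panel, "instrument_dna")
  el_col <- .instrument_col(panel, "instrument_event_length")
  n_in <- n_events(m)
  dna <- m$values[, dna_col]
  keep <- dna >= params$dna_bounds[1] & dna <= params$dna_bounds[2] &
    m$values[, el_col] <= params$event_length_max
  m <- .subset_events(m, keep)
  record("singlet_selection", n_in, n_events(m))

  via_col <- .instrument_col(panel, "instrument_viability")
  n_in <- n_events(m)
  keep <- m$values[, via_col] <= params$viability_max
  m <- .subset_events(m, keep)
  record("viability", n_in, n_events(m))

  cd45_col <- .marker_col(panel, "CD45")
  lin_cols <- setdiff(which(panel$channels$category == "lineage"), cd45_col)
  n_in <- n_events(m)
  keep <- m$values[, cd45_col] <= params$cd45_max
  if (length(lin_cols)) {
    keep <- keep & rowSums(m$values[, lin_cols, drop = FALSE] >
                             params$lineage_max) == 0
  }
  m <- .subset_events(m, keep)
  record("lin_cd45_negative", n_in, n_events(m))

  qc <- do.call(rbind, stages)
  list(matrix = m, qc = qc)
}

#' Subsample events without replacement
#'
#' Draws `n` events uniformly without replacement (all events when `n`
#' exceeds the count), reproducibly for a given seed; acquisition order of
#' the selected events is preserved.
#'
#' @param matrix a `senocyto_events`.
#' @param n number of events to keep.
#' @param seed integer seed.
#' @return Subsampled `senocyto_events`.
#' @export
subsample_events <- function(matrix, n, seed = 1L) {
  stopifnot(inherits(matrix, "senocyto_events"), n >= 0)
  total <- n_events(matrix)
  if (n >= total) return(matrix)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  keep <- sort(sample.int(total, n))
  .subset_events(matrix, keep)
}

#' Standard preprocessing chain
#'
#' Bead normalization, arcsinh transform, data-driven cleanup parameters and
#' sequential cleanup gating in one call.
#'
#' @param matrix raw-scale `senocyto_events`.
#' @param cofactor arcsinh cofactor.
#' @param n_bins bead-normalization bins.
#' @param params optional pre-computed cleanup parameters; derived from the
#'   data when `NULL`.
#' @return List with `matrix` (cleaned, transformed), `qc`, and `params`.
#' @export
preprocess_sample <- function(matrix, cofactor = 5, n_bins = 20,
                              params = NULL) {
  m <- bead_normalize(matrix, n_bins = n_bins)
  m <- arcsinh_transform(m, cofactor = cofactor)
  if (is.null(params)) params <- default_cleanup_params(m)
  res <- cleanup_gate(m, params)
  res$params <- params
  res
}
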