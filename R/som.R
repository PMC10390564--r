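# Self-organizing map: batch training with a linearly shrinking Gaussian
# neighborhood. Batch updates are sums over events, so training is
# independent of event order; initialization is a seeded draw around the
# per-channel means, which is likewise order-independent.

#' Train a self-organizing map
#'
#' Batch SOM on the selected clustering channels. Each epoch assigns every
#' event to its best-matching node and replaces each code vector by the
#' neighborhood-weighted mean of the events, with the Gaussian neighborhood
#' radius shrinking linearly from half the grid diagonal to 0.5 over the
#' epochs. The quantization-error trace (mean event-to-node distance per
#' epoch) is recorded.
#'
#' @param matrix transformed `senocyto_events`.
#' @param channels clustering channels (marker names); defaults to the
#'   panel's identity markers.
#' @param grid `(rows, cols)` of the node grid.
#' @param epochs training epochs.
#' @param seed integer seed (initialization only; updates are
#'   deterministic).
#' @return A `senocyto_som`: code vectors, grid shape, channels, per-event
#'   node mapping, occupancy, and the quantization-error trace.
#' @export
train_som <- function(matrix, channels = NULL, grid = c(10, 10),
                      epochs = 10, seed = 1L) {
  stopifnot(inherits(matrix, "senocyto_events"))
  if (!matrix$transformed) stop("train_som expects arcsinh-transformed data")
  if (is.null(channels)) channels <- panel_markers(matrix$panel, "identity")
  x <- matrix$values[, .marker_col(matrix$panel, channels), drop = FALSE]
  n <- nrow(x)
  n_nodes <- grid[1] * grid[2]
  if (n < n_nodes) {
    stop("fewer events (", n, ") than nodes (", n_nodes,
         "); use a smaller grid")
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  codes <- matrix(stats::rnorm(n_nodes * ncol(x)), nrow = n_nodes) *
    rep(sdev, each = n_nodes) + rep(mu, each = n_nodes)

  # grid coordinates and squared grid distances
  coords <- cbind(rep(seq_len(grid[1]), times = grid[2]),
                  rep(seq_len(grid[2]), each = grid[1]))
  gd2 <- as.matrix(stats::dist(coords))^2

  bmu_of <- function(codes) {
    # nearest code vector per event via the expanded squared distance
    cross <- x %*% t(codes)
    d2 <- outer(rep(1, n), rowSums(codes^2)) - 2 * cross
    max.col(-d2, ties.method = "first")
  }

  sigma0 <- max(grid) / 2
  sigma1 <- 0.5
  trace <- numeric(epochs)
  bmu <- bmu_of(codes)
  for (e in seq_len(epochs)) {
    sigma <- sigma0 + (sigma1 - sigma0) * (e - 1) / max(epochs - 1, 1)
    h <- exp(-gd2 / (2 * sigma^2))
    agg <- rowsum(x, bmu)
    sums <- matrix(0, n_nodes, ncol(x))
    sums[as.integer(rownames(agg)), ] <- agg
    counts <- tabulate(bmu, nbins = n_nodes)
    numer <- h %*% sums
    denom <- as.vector(h %*% counts)
    upd <- denom > 1e-12
    codes[upd, ] <- numer[upd, , drop = FALSE] / denom[upd]
    bmu <- bmu_of(codes)
    trace[e] <- mean(sqrt(pmax(
      rowSums(x^2) + rowSums(codes^2)[bmu] - 2 * rowSums(x * codes[bmu, , drop = FALSE]),
      0)))
  }
  structure(list(codes = codes, grid = grid, channels = channels,
                 mapping = bmu, occupancy = tabulate(bmu, nbins = n_nodes),
                 qe_trace = trace, seed = seed),
            class = "senocyto_som")
}

#' @export
print.senocyto_som <- function(x, ...) {
  cat("senocyto SOM: ", x$grid[1], "x", x$grid[2], " grid on ",
      length(x$channels), " channels; final quantization error ",
      signif(utils::tail(x$qe_trace, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Map events to SOM nodes
#'
#' @param model a `senocyto_som`.
#' @param matrix transformed `senocyto_events` on the same channels.
#' @return Integer vector of best-matching node ids, one per event.
#' @export
map_to_nodes <- function(model, matrix) {
  x <- matrix$values[, .marker_col(matrix$panel, model$channels), drop = FALSE]
  cross <- x %*% t(model$codes)
  d2 <- outer(rep(1, nrow(x)), rowSums(model$codes^2)) - 2 * cross
  max.col(-d2, ties.method = "first")
}
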