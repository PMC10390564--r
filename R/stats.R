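# Group-comparison statistics: Shapiro-Wilk-routed tests, Holm-Sidak
# step-down correction, and heatmap row scaling.

#' Route a two-group comparison to a parametric or nonparametric test
#'
#' Shapiro-Wilk normality is checked in each group; a p-value below 0.05 in
#' either routes the comparison to the two-sided Mann-Whitney test, otherwise
#' to the Welch two-sided t test. Groups with fewer than three values, or
#' constant groups (normality undefined), force the nonparametric route with
#' a warning.
#'
#' @param values_a,values_b numeric group values.
#' @param alpha Shapiro-Wilk significance level for rejecting normality.
#' @return `"t_test"` or `"mann_whitney"`.
#' @export
route_test <- function(values_a, values_b, alpha = 0.05) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3) {
    warning("fewer than 3 values in a group; forcing Mann-Whitney")
    return("mann_whitney")
  }
  sw_p <- function(x) {
    if (stats::sd(x) == 0) return(0)  # degenerate: route nonparametric
    stats::shapiro.test(x)$p.value
  }
  if (sw_p(values_a) < alpha || sw_p(values_b) < alpha) {
    "mann_whitney"
  } else {
    "t_test"
  }
}

#' Two-group comparison with routed test and fold change
#'
#' Two-sided p from the routed test (Welch t or Mann-Whitney; the
#' Mann-Whitney uses exact enumeration for group sizes of at most 8 without
#' ties and the tie-corrected normal approximation otherwise) plus the log2
#' fold change of group means (comparison over reference).
#'
#' @param values_a reference-group values.
#' @param values_b comparison-group values.
#' @param unit free-text label of what is being compared.
#' @param test override the routing (`NULL` = route automatically).
#' @return data.frame row: unit, test_used, statistic, p_raw,
#'   log2_fold_change, mean_a, mean_b.
#' @export
compare_groups <- function(values_a, values_b, unit = "value", test = NULL) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (is.null(test)) {
    test <- suppressWarnings(route_test(values_a, values_b))
  }
  identical_const <- length(unique(c(values_a, values_b))) == 1
  if (identical_const) {
    stat <- NA_real_
    p <- 1
  } else if (test == "t_test") {
    tt <- stats::t.test(values_b, values_a, var.equal = FALSE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    exact <- length(values_a) <= 8 && length(values_b) <= 8 &&
      !anyDuplicated(c(values_a, values_b))
    wt <- suppressWarnings(
      stats::wilcox.test(values_b, values_a, exact = exact, correct = !exact))
    stat <- unname(wt$statistic)
    p <- wt$p.value
  }
  ma <- mean(values_a)
  mb <- mean(values_b)
  l2fc <- if (ma == 0 || mb == 0 || sign(ma) != sign(mb)) {
    if (ma == mb) 0 else NA_real_
  } else {
    log2(mb / ma)
  }
  data.frame(unit = unit, test_used = test, statistic = stat, p_raw = p,
             log2_fold_change = l2fc, mean_a = ma, mean_b = mb,
             stringsAsFactors = FALSE)
}

#' Holm-Sidak step-down adjustment
#'
#' With m p-values sorted ascending, the i-th adjusted value is
#' `max_{j <= i} (1 - (1 - p_(j))^(m - j + 1))`, capped at 1, returned in
#' the original order. Controls the family-wise error rate; never rejects
#' more than unadjusted testing at the same level.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return data.frame with `p_raw` and `p_adjusted` in input order.
#' @export
holm_sidak <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  m <- length(p_values)
  if (m == 0) return(data.frame(p_raw = numeric(0), p_adjusted = numeric(0)))
  ord <- order(p_values)
  ps <- p_values[ord]
  adj <- pmin(cummax(1 - (1 - ps)^(m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[ord] <- adj
  data.frame(p_raw = p_values, p_adjusted = out)
}

#' Row-standardize a profile matrix for heatmap display
#'
#' Subtracts the row mean and divides by the row standard deviation
#' (population convention: divisor n, not n-1, for bit-stable output).
#' Constant rows are returned as all zeros with a warning.
#'
#' @param profile numeric matrix (e.g. clusters x markers).
#' @return Matrix of the same shape with row mean 0 and population SD 1.
#' @export
scale_heatmap <- function(profile) {
  profile <- as.matrix(profile)
  if (ncol(profile) < 2) stop("scale_heatmap needs at least 2 columns per row")
  mu <- rowMeans(profile)
  centered <- profile - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  zero <- sd_pop < .Machine$double.eps^0.5
  if (any(zero)) {
    warning(sum(zero), " constant row(s) returned as zeros")
    sd_pop[zero] <- 1
    centered[zero, ] <- 0
  }
  centered / sd_pop
}
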