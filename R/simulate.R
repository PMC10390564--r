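# Synthetic cytometry cohort simulator.
#
# Generates multi-sample event matrices with the statistical structure the
# downstream analysis assumes: an 11-population mesenchymal mixture,
# age/treatment-dependent senescent subfractions organized into archetypes,
# bead/doublet/dead-cell/debris/CD45+ contamination, slow acquisition drift,
# and full per-event ground truth.

#' Load a simulation configuration
#'
#' @param path YAML file (see the shipped `config/default_cohort.yaml` for
#'   the full schema).
#' @return A validated `senocyto_simconfig`.
#' @export
load_simulation_config <- function(path) {
  if (!file.exists(path)) stop("simulation config not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_simulation_config(cfg)
}

#' Default cohort calibration
#'
#' The shipped configuration encodes the published group prevalences of
#' p16+ and p21+ cells, the p16KB conditional rates, the between-animal
#' dispersions, the 11-population mesenchymal mixture and the six p16+
#' senescence archetypes.
#'
#' @return A `senocyto_simconfig`.
#' @export
default_simulation_config <- function() {
  path <- system.file("extdata", "config", "default_cohort.yaml",
                      package = "senocyto")
  if (!nzchar(path)) stop("default cohort config not installed")
  load_simulation_config(path)
}

#' Validate a simulation configuration
#'
#' Checks fraction ranges, per-group mixture-weight sums (populations and
#' archetypes must each sum to one per group) and presence of required
#' blocks.
#'
#' @param cfg configuration list.
#' @return The configuration, classed `senocyto_simconfig`.
#' @export
validate_simulation_config <- function(cfg) {
  need <- c("events_per_sample", "cofactor", "contamination", "signals",
            "marker_levels", "prevalence", "dispersion", "base_rates",
            "conditional", "archetypes", "populations", "thresholds")
  missing_blk <- setdiff(need, names(cfg))
  if (length(missing_blk)) {
    stop("simulation configuration error: missing block(s) ",
         paste(missing_blk, collapse = ", "))
  }
  if (cfg$events_per_sample < 1) {
    stop("simulation configuration error: events_per_sample must be >= 1")
  }
  frac <- unlist(cfg$contamination)
  if (any(frac < 0 | frac > 1) || sum(frac) >= 1) {
    stop("simulation configuration error: contamination fractions must lie in [0,1] and sum below 1")
  }
  groups <- names(cfg$prevalence$p16)
  for (g in groups) {
    for (m in names(cfg$prevalence)) {
      p <- cfg$prevalence[[m]][[g]]
      if (is.null(p) || p < 0 || p > 1) {
        stop("simulation configuration error: prevalence ", m, "/", g,
             " missing or outside [0,1]")
      }
    }
    wpop <- vapply(cfg$populations, function(p) {
      w <- p$weight[[g]]
      if (is.null(w)) stop("simulation configuration error: population '",
                           p$name, "' lacks weight for group ", g)
      w
    }, numeric(1))
    if (abs(sum(wpop) - 1) > 1e-6) {
      stop("simulation configuration error: population weights for group ",
           g, " sum to ", sum(wpop), ", not 1")
    }
    warc <- vapply(cfg$archetypes, function(a) {
      w <- a$weight[[g]]
      if (is.null(w)) stop("simulation configuration error: archetype '",
                           a$name, "' lacks weight for group ", g)
      w
    }, numeric(1))
    if (abs(sum(warc) - 1) > 1e-6) {
      stop("simulation configuration error: archetype weights for group ",
           g, " sum to ", sum(warc), ", not 1")
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- c("senocyto_simconfig", "list")
  cfg
}

#' Default cohort design
#'
#' Mirrors the study arms: 15 young, 12 old + vehicle, 13 old + senolytic,
#' plus (optionally) one young p16 knock-out control used for threshold
#' derivation only.
#'
#' @param n_young,n_old,n_senolytic group sizes.
#' @param ko_control include a knock-out control sample.
#' @return A `senocyto_design` data.frame.
#' @export
default_cohort_design <- function(n_young = 15, n_old = 12, n_senolytic = 13,
                                  ko_control = TRUE) {
  d <- data.frame(
    sample_id = c(sprintf("young_%02d", seq_len(n_young)),
                  sprintf("old_%02d", seq_len(n_old)),
                  sprintf("senolytic_%02d", seq_len(n_senolytic))),
    age_group = c(rep("young", n_young), rep("old", n_old + n_senolytic)),
    treatment = c(rep("none", n_young), rep("vehicle", n_old),
                  rep("senolytic", n_senolytic)),
    genotype = "wildtype",
    stringsAsFactors = FALSE
  )
  if (ko_control) {
    d <- rbind(d, data.frame(sample_id = "ko_control_01", age_group = "young",
                             treatment = "none", genotype = "ko_control",
                             stringsAsFactors = FALSE))
  }
  cohort_design(d)
}

# Deterministic per-sample seed from (master seed, sample id): a small
# polynomial string hash folded into [0, 2^31 - 2].
.stable_seed <- function(master, sample_id) {
  h <- as.double(master %% 2147483647)
  for (code in utf8ToInt(as.character(sample_id))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Draw arcsinh-scale intensities for m cell events: background everywhere,
# population identity means on expressed markers. Returns list(values,
# population index).
.draw_cell_block <- function(m, group, cfg, panel, pop_idx = NULL) {
  sg <- cfg$signals
  markers <- panel$channels$marker
  nch <- length(markers)
  vals <- matrix(stats::rnorm(m * nch, sg$background_mean, sg$background_sd),
                 nrow = m, ncol = nch)
  colnames(vals) <- markers
  weights <- vapply(cfg$populations, function(p) p$weight[[group]], numeric(1))
  if (is.null(pop_idx)) {
    pop_idx <- sample.int(length(weights), m, replace = TRUE, prob = weights)
  }
  for (pi in unique(pop_idx)) {
    rows <- which(pop_idx == pi)
    for (mk in names(cfg$populations[[pi]]$markers)) {
      mu <- cfg$populations[[pi]]$markers[[mk]]
      col <- .marker_col(panel, mk)
      vals[rows, col] <- stats::rnorm(length(rows), mu, sg$positive_sd)
    }
  }
  # instrument channels for intact single cells
  vals[, .instrument_col(panel, "instrument_dna")] <-
    stats::rnorm(m, sg$dna_mean, sg$dna_sd)
  vals[, .instrument_col(panel, "instrument_viability")] <-
    stats::rnorm(m, sg$viability_live_mean, sg$viability_live_sd)
  vals[, .instrument_col(panel, "instrument_bead")] <-
    stats::rnorm(m, sg$background_mean / 2, sg$background_sd / 2)
  el_raw <- stats::rnorm(m, sg$event_length_raw_mean, sg$event_length_raw_sd)
  vals[, .instrument_col(panel, "instrument_event_length")] <-
    asinh(pmax(el_raw, 1) / cfg$cofactor)
  list(values = vals, pop = pop_idx)
}

#' Simulate one sample
#'
#' Events are drawn in acquisition order: a contamination class per event,
#' then for cells a population by the group's mixture weights, marker
#' intensities normal on the arcsinh scale inverse-transformed to the raw
#' ion-count scale (truncated at zero), senescence flags by the group's
#' (dispersion-jittered) prevalences, archetypes and conditional rates,
#' doublets as sums of two independent cells with DNA and event length
#' scaled by the configured multiplier, beads carrying the calibration
#' signal, and a multiplicative linear drift across the acquisition applied
#' to every metal channel.
#'
#' @param config a `senocyto_simconfig`.
#' @param group `"young"`, `"old"` or `"old_senolytic"`.
#' @param sample_seed integer seed for this sample.
#' @param panel panel to simulate; defaults to [default_panel()].
#' @param n_events number of acquired events; defaults to the config value.
#' @param sample_id sample identifier stored in the output.
#' @param ko_control simulate a p16-null control (p16 prevalence forced to
#'   zero; the p16 channel carries only background).
#' @return A raw-scale `senocyto_events` with a truth table (`population`,
#'   `class`, `archetype`, and logical flags `p16_true`, `p21_true`,
#'   `ki67_true`, `bcl2_true`, `p16kb_true`, `p21kb_true`).
#' @export
simulate_sample <- function(config, group, sample_seed,
                            panel = default_panel(),
                            n_events = config$events_per_sample,
                            sample_id = paste0(group, "_", sample_seed),
                            ko_control = FALSE) {
  stopifnot(inherits(config, "senocyto_simconfig"))
  if (is.null(config$prevalence$p16[[group]])) {
    stop("simulation configuration error: group '", group,
         "' missing from prevalence maps")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(sample_seed)

  sg <- config$signals
  cofactor <- config$cofactor
  n <- n_events
  cont <- config$contamination
  classes <- c("bead", "doublet", "dead", "debris", "cd45pos", "cell")
  probs <- c(cont$beads, cont$doublets, cont$dead, cont$debris, cont$cd45pos)
  probs <- c(probs, 1 - sum(probs))
  cls <- sample(classes, n, replace = TRUE, prob = probs)

  cellular <- cls %in% c("cell", "dead", "doublet")
  block <- .draw_cell_block(n, group, config, panel)
  vals <- block$values
  pop_idx <- block$pop
  pop_names <- vapply(config$populations, function(p) p$name, character(1))
  markers <- panel$channels$marker
  i_dna <- .instrument_col(panel, "instrument_dna")
  i_via <- .instrument_col(panel, "instrument_viability")
  i_bead <- .instrument_col(panel, "instrument_bead")
  i_el <- .instrument_col(panel, "instrument_event_length")
  metal_cols <- setdiff(seq_along(markers), i_el)

  # ---- senescence flags (clean cells only; prevalences are defined over
  # the cleaned Lin-CD45- compartment) -------------------------------------
  is_cell <- cls == "cell"
  m_cell <- sum(is_cell)
  disp <- config$dispersion[[group]]
  jitter1 <- exp(stats::rnorm(1, 0, disp) - disp^2 / 2)
  jitter2 <- exp(stats::rnorm(1, 0, disp) - disp^2 / 2)
  prev16 <- min(if (ko_control) 0 else config$prevalence$p16[[group]] * jitter1, 0.5)
  prev21 <- min(config$prevalence$p21[[group]] * jitter2, 0.5)

  enrich <- vapply(config$populations, function(p) p$enrichment, numeric(1))
  wpop <- vapply(config$populations, function(p) p$weight[[group]], numeric(1))
  mean_enrich <- sum(wpop * enrich)
  rate16 <- pmin(prev16 * enrich / mean_enrich, 0.9)

  p16_true <- p21_true <- ki67_true <- bcl2_true <- logical(n)
  archetype <- rep(NA_character_, n)
  cell_rows <- which(is_cell)
  p16_true[cell_rows] <- stats::runif(m_cell) < rate16[pop_idx[cell_rows]]
  # p16 and p21 carriers are modeled as disjoint (the published overlap is
  # minimal); p21 rate among non-p16 cells is scaled to hit the overall
  # prevalence.
  p21_rate <- if (prev16 >= 1) 0 else min(prev21 / (1 - prev16), 1)
  p21_true[cell_rows] <- !p16_true[cell_rows] &
    stats::runif(m_cell) < p21_rate

  arc_names <- vapply(config$archetypes, function(a) a$name, character(1))
  arc_w <- vapply(config$archetypes, function(a) a$weight[[group]], numeric(1))
  bcl2_fam <- vapply(config$archetypes, function(a) isTRUE(a$bcl2_family), logical(1))
  ki67_fam <- vapply(config$archetypes, function(a) isTRUE(a$ki67_family), logical(1))
  p16_rows <- which(p16_true)
  if (length(p16_rows)) {
    ai <- sample.int(length(arc_names), length(p16_rows), replace = TRUE,
                     prob = arc_w)
    archetype[p16_rows] <- arc_names[ai]
    bcl2_true[p16_rows] <- bcl2_fam[ai]
    u <- stats::runif(length(p16_rows))
    other_leak <- config$conditional$ki67_pos_given_nonki67_archetype
    if (is.null(other_leak)) other_leak <- config$base_rates$ki67
    ki67_true[p16_rows] <- ifelse(
      ki67_fam[ai], TRUE,
      ifelse(bcl2_fam[ai],
             u < config$conditional$ki67_pos_given_bcl2_archetype,
             u < other_leak))
  }
  p21_rows <- which(p21_true)
  if (length(p21_rows)) {
    bcl2_true[p21_rows] <- stats::runif(length(p21_rows)) <
      config$conditional$bcl2_given_p21
    ki67_true[p21_rows] <- stats::runif(length(p21_rows)) < ifelse(
      bcl2_true[p21_rows], config$conditional$ki67_pos_given_p21_bcl2,
      config$base_rates$ki67)
  }
  plain_rows <- setdiff(cell_rows, c(p16_rows, p21_rows))
  if (length(plain_rows)) {
    bcl2_true[plain_rows] <- stats::runif(length(plain_rows)) <
      config$base_rates$bcl2
    ki67_true[plain_rows] <- stats::runif(length(plain_rows)) <
      config$base_rates$ki67
  }
  p16kb_true <- p16_true & bcl2_true & !ki67_true
  p21kb_true <- p21_true & bcl2_true & !ki67_true

  # ---- flag-driven marker levels -----------------------------------------
  set_level <- function(rows, marker, mu) {
    if (length(rows) == 0) return()
    col <- .marker_col(panel, marker)
    vals[rows, col] <<- stats::rnorm(length(rows), mu, sg$positive_sd)
  }
  lv <- config$marker_levels
  set_level(which(p16_true), "p16", lv[["p16"]])
  set_level(which(p21_true), "p21", lv[["p21"]])
  # Ki67+ cells inside non-proliferative p16+ archetypes express residual
  # low-grade Ki67 (still above the positivity cutoff); everyone else
  # Ki67-positive carries the full proliferation level.
  ki67_fam_rows <- which(ki67_true & !is.na(archetype) &
                           archetype %in% arc_names[ki67_fam])
  ki67_low_rows <- setdiff(which(ki67_true & p16_true), ki67_fam_rows)
  ki67_full_rows <- setdiff(which(ki67_true), ki67_low_rows)
  set_level(ki67_full_rows, "Ki67", lv[["Ki67"]])
  low_level <- if (is.null(lv[["Ki67_low"]])) lv[["Ki67"]] else lv[["Ki67_low"]]
  set_level(ki67_low_rows, "Ki67", low_level)
  set_level(which(bcl2_true), "BCL-2", lv[["BCL-2"]])
  if (!ko_control) set_level(which(p16_true), "FLAG", lv[["FLAG"]])
  for (a in config$archetypes) {
    rows <- which(!is.na(archetype) & archetype == a$name)
    if (!length(rows) || !length(a$shifts)) next
    for (mk in names(a$shifts)) {
      col <- .marker_col(panel, mk)
      vals[rows, col] <- vals[rows, col] + a$shifts[[mk]]
    }
  }

  # ---- contamination classes ---------------------------------------------
  rows_bead <- which(cls == "bead")
  if (length(rows_bead)) {
    mb <- length(rows_bead)
    vals[rows_bead, ] <- matrix(abs(stats::rnorm(mb * ncol(vals), 0.05, 0.05)),
                                nrow = mb)
    vals[rows_bead, i_el] <- asinh(
      pmax(stats::rnorm(mb, sg$bead_event_length_raw_mean,
                        sg$event_length_raw_sd), 1) / cofactor)
    pop_idx[rows_bead] <- NA
  }
  rows_debris <- which(cls == "debris")
  if (length(rows_debris)) {
    md <- length(rows_debris)
    vals[rows_debris, ] <- matrix(
      stats::rnorm(md * ncol(vals), sg$background_mean / 2, sg$background_sd / 2),
      nrow = md)
    vals[rows_debris, i_dna] <- stats::rnorm(md, sg$debris_dna_mean, sg$debris_dna_sd)
    vals[rows_debris, i_via] <- stats::rnorm(md, sg$viability_live_mean,
                                             sg$viability_live_sd)
    vals[rows_debris, i_el] <- asinh(
      pmax(stats::rnorm(md, sg$debris_event_length_raw_mean,
                        sg$event_length_raw_sd), 1) / cofactor)
    pop_idx[rows_debris] <- NA
  }
  rows_cd45 <- which(cls == "cd45pos")
  if (length(rows_cd45)) {
    mc <- length(rows_cd45)
    # hematopoietic carryover: identity markers at background, CD45/lineage high
    ident_cols <- which(panel$channels$category %in%
                          c("identity", "senescence", "sasp", "dna_damage",
                            "anti_apoptosis", "proliferation", "transgene"))
    vals[rows_cd45, ident_cols] <- matrix(
      stats::rnorm(mc * length(ident_cols), sg$background_mean, sg$background_sd),
      nrow = mc)
    vals[rows_cd45, .marker_col(panel, "CD45")] <-
      stats::rnorm(mc, sg$cd45_pos_mean, sg$positive_sd)
    lin_cols <- setdiff(which(panel$channels$category == "lineage"),
                        .marker_col(panel, "CD45"))
    for (col in lin_cols) {
      vals[rows_cd45, col] <- stats::rnorm(mc, sg$lineage_pos_mean, sg$positive_sd)
    }
    pop_idx[rows_cd45] <- NA
  }
  rows_dead <- which(cls == "dead")
  if (length(rows_dead)) {
    vals[rows_dead, i_via] <- stats::rnorm(length(rows_dead),
                                           sg$viability_dead_mean,
                                           sg$viability_dead_sd)
  }

  # ---- to raw scale; doublets sum two cells on the raw scale --------------
  raw <- pmax(sinh(vals) * cofactor, 0)
  rows_dbl <- which(cls == "doublet")
  if (length(rows_dbl)) {
    partner <- .draw_cell_block(length(rows_dbl), group, config, panel)
    raw_partner <- pmax(sinh(partner$values) * cofactor, 0)
    ab_cols <- setdiff(metal_cols, c(i_dna, i_via, i_bead))
    raw[rows_dbl, ab_cols] <- raw[rows_dbl, ab_cols] + raw_partner[, ab_cols]
    mult <- stats::runif(length(rows_dbl), sg$doublet_multiplier[[1]],
                         sg$doublet_multiplier[[2]])
    raw[rows_dbl, i_dna] <- raw[rows_dbl, i_dna] * mult
    raw[rows_dbl, i_el] <- pmax(
      cofactor * sinh(vals[rows_dbl, i_el]), 1) * mult
    pop_idx[rows_dbl] <- NA
  }
  if (length(rows_bead)) {
    raw[rows_bead, i_bead] <- sg$bead_raw_signal *
      exp(stats::rnorm(length(rows_bead), 0, sg$bead_raw_cv))
  }

  # ---- acquisition drift on every metal channel ---------------------------
  slope <- config$drift_slope
  if (!is.null(slope) && slope != 0 && n > 1) {
    g <- 1 + slope * ((seq_len(n) - 1) / (n - 1) - 0.5)
    raw[, metal_cols] <- raw[, metal_cols] * g
  }

  truth <- data.frame(
    population = ifelse(is.na(pop_idx), NA_character_, pop_names[pop_idx]),
    class = cls,
    archetype = archetype,
    p16_true = p16_true, p21_true = p21_true, ki67_true = ki67_true,
    bcl2_true = bcl2_true, p16kb_true = p16kb_true, p21kb_true = p21kb_true,
    stringsAsFactors = FALSE
  )
  truth$population[truth$class != "cell" & truth$class != "dead"] <- NA

  event_matrix(raw, panel, sample_id = sample_id, truth = truth)
}

#' Simulate a cohort
#'
#' One event matrix per design row. Per-sample seeds are derived
#' deterministically from `(config$seed, sample_id)` via a stable string
#' hash, so regeneration is bitwise-identical and per-sample draws are
#' independent. Knock-out-control rows are simulated with zero p16
#' prevalence.
#'
#' @param config a `senocyto_simconfig`.
#' @param design a `senocyto_design`.
#' @param panel panel to simulate.
#' @param n_events events per sample (default from config).
#' @return Named list of `senocyto_events`, one per design row.
#' @export
simulate_cohort <- function(config, design, panel = default_panel(),
                            n_events = config$events_per_sample) {
  stopifnot(inherits(design, "senocyto_design"))
  out <- vector("list", nrow(design))
  names(out) <- design$sample_id
  for (i in seq_len(nrow(design))) {
    ko <- design$genotype[i] == "ko_control"
    group <- if (ko) design$age_group[i] else design$group[i]
    if (group == "old" && !ko && design$treatment[i] == "senolytic") {
      group <- "old_senolytic"
    }
    out[[i]] <- simulate_sample(
      config, group = group,
      sample_seed = .stable_seed(config$seed, design$sample_id[i]),
      panel = panel, n_events = n_events,
      sample_id = design$sample_id[i], ko_control = ko)
  }
  out
}

#' Per-sample truth prevalence table
#'
#' Percentages of clean cells (contamination classes excluded from the
#' denominator) carrying each truth flag.
#'
#' @param matrices list of simulated `senocyto_events` with truth labels.
#' @return data.frame with one row per sample.
#' @export
truth_summary <- function(matrices) {
  if (inherits(matrices, "senocyto_events")) matrices <- list(matrices)
  if (length(matrices) == 0) {
    return(data.frame(sample_id = character(0), n_clean = integer(0),
                      pct_p16 = numeric(0), pct_p21 = numeric(0),
                      pct_p16kb = numeric(0), pct_p21kb = numeric(0)))
  }
  rows <- lapply(matrices, function(m) {
    if (is.null(m$truth)) stop("truth labels missing for sample ", m$sample_id)
    tr <- m$truth[m$truth$class == "cell", , drop = FALSE]
    nc <- nrow(tr)
    pct <- function(flag) if (nc == 0) NA_real_ else 100 * sum(tr[[flag]]) / nc
    data.frame(sample_id = m$sample_id, n_clean = nc,
               pct_p16 = pct("p16_true"), pct_p21 = pct("p21_true"),
               pct_p16kb = pct("p16kb_true"), pct_p21kb = pct("p21kb_true"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pool event matrices with sample provenance
#'
#' Optionally subsamples a fixed number of events per sample (seeded,
#' without replacement) before pooling; the returned matrix carries a
#' per-event `sample` vector.
#'
#' @param matrices list of `senocyto_events` sharing one panel and scale.
#' @param n_per_sample optional per-sample subsample size.
#' @param seed seed for subsampling.
#' @return A `senocyto_events` with element `sample` (per-event sample id).
#' @export
pool_events <- function(matrices, n_per_sample = NULL, seed = 1L) {
  stopifnot(length(matrices) >= 1)
  tfm <- unique(vapply(matrices, function(m) m$transformed, logical(1)))
  if (length(tfm) != 1) stop("cannot pool matrices on mixed scales")
  if (!is.null(n_per_sample)) {
    # per-sample seeds hash the sample id so pooling is independent of the
    # order in which samples are supplied
    matrices <- lapply(matrices, function(m) {
      subsample_events(m, n_per_sample,
                       seed = .stable_seed(seed, m$sample_id))
    })
  }
  vals <- do.call(rbind, lapply(matrices, function(m) m$values))
  sample_vec <- unlist(lapply(matrices, function(m) {
    rep(m$sample_id, n_events(m))
  }), use.names = FALSE)
  truths <- lapply(matrices, function(m) m$truth)
  truth <- if (!any(vapply(truths, is.null, logical(1)))) {
    do.call(rbind, truths)
  } else NULL
  out <- event_matrix(vals, matrices[[1]]$panel, sample_id = "pooled",
                      transformed = tfm, truth = truth)
  out$sample <- sample_vec
  out
}
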