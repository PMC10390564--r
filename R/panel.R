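# Panel definitions, channel semantics and cohort designs.
#
# The panel is the single source of channel meaning for every downstream
# stage: which metals carry identity markers, which carry the senescence /
# SASP readouts, and which are instrument channels (DNA intercalator,
# viability stain, calibration beads, event length).

#' Valid channel categories
#'
#' Category vocabulary for panel channels. `identity` markers define cell
#' populations and drive clustering; `senescence`, `sasp`, `dna_damage`,
#' `anti_apoptosis` and `proliferation` form the senescence phenotyping panel;
#' `lineage` channels are used for Lin-/CD45- negative selection;
#' `instrument_*` channels support cleanup gating and drift correction.
#'
#' @return Character vector of valid categories.
#' @export
channel_categories <- function() {
  c("identity", "senescence", "sasp", "dna_damage", "anti_apoptosis",
    "proliferation", "transgene", "lineage",
    "instrument_bead", "instrument_dna", "instrument_viability",
    "instrument_event_length")
}

# Marker aliases: panel tables mix capitalizations and punctuation
# (BCL-2 / Bcl-2, PDGFRa / CD140a). Canonicalization strips case, dashes,
# spaces and slashes before comparison.
.canon_marker <- function(x) {
  x <- tolower(x)
  gsub("[-_/ ]", "", x)
}

.marker_alias <- c(
  "bcl2"      = "BCL-2",
  "cd140a"    = "PDGFRa",
  "pdgfralpha" = "PDGFRa",
  "sdf1"      = "CXCL12",
  "itga11"    = "OsteolectinR",
  "sp7"       = "Osterix",
  "ppary"     = "Pparg",
  "ppargamma" = "Pparg",
  "gh2ax"     = "yH2A-X",
  "yh2ax"     = "yH2A-X",
  "ki67"      = "Ki67"
)

.resolve_marker_name <- function(x) {
  key <- .canon_marker(x)
  hit <- .marker_alias[key]
  ifelse(is.na(hit), x, hit)
}

#' Construct a panel definition
#'
#' @param channels data.frame with columns `marker`, `metal`, `category`
#'   (one row per channel, in acquisition order).
#' @param version free-text panel version tag.
#' @return An object of class `senocyto_panel`.
#' @export
panel_definition <- function(channels, version = "unversioned") {
  stopifnot(is.data.frame(channels))
  need <- c("marker", "metal", "category")
  missing_cols <- setdiff(need, names(channels))
  if (length(missing_cols)) {
    stop("panel table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(channels) == 0L) {
    stop("panel configuration error: empty channel list")
  }
  channels <- data.frame(
    marker = as.character(channels$marker),
    metal = as.character(channels$metal),
    category = as.character(channels$category),
    stringsAsFactors = FALSE
  )
  channels$marker <- .resolve_marker_name(channels$marker)

  bad_cat <- setdiff(unique(channels$category), channel_categories())
  if (length(bad_cat)) {
    stop("panel configuration error: unknown category ",
         paste(bad_cat, collapse = ", "))
  }
  dup_metal <- channels$metal[duplicated(channels$metal)]
  if (length(dup_metal)) {
    stop("panel configuration error: duplicate metal tag ",
         paste(unique(dup_metal), collapse = ", "))
  }
  canon <- .canon_marker(channels$marker)
  dup_marker <- channels$marker[duplicated(canon)]
  if (length(dup_marker)) {
    stop("panel configuration error: duplicate marker ",
         paste(unique(dup_marker), collapse = ", "))
  }
  singleton <- c("instrument_dna", "instrument_viability",
                 "instrument_event_length")
  for (cat in singleton) {
    if (sum(channels$category == cat) > 1L) {
      stop("panel configuration error: category ", cat,
           " must appear at most once")
    }
  }
  structure(list(channels = channels, version = version),
            class = "senocyto_panel")
}

#' @export
print.senocyto_panel <- function(x, ...) {
  cat("senocyto panel (", x$version, "): ", nrow(x$channels),
      " channels\n", sep = "")
  tab <- table(x$channels$category)
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Load a panel definition from YAML or JSON
#'
#' The file holds a list of channel entries with fields `marker`, `metal`
#' and `category`, plus an optional top-level `version`. Both a top-level
#' list and a `channels:` block are accepted.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` panel file.
#' @return A `senocyto_panel`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  version <- "unversioned"
  entries <- raw
  if (!is.null(names(raw)) && "channels" %in% names(raw)) {
    entries <- raw$channels
    if (!is.null(raw$version)) version <- as.character(raw$version)
  }
  if (length(entries) == 0L) {
    stop("panel configuration error: empty channel list")
  }
  rows <- lapply(entries, function(e) {
    if (is.null(e$marker) || is.null(e$metal) || is.null(e$category)) {
      stop("panel configuration error: each channel needs marker, metal, category")
    }
    data.frame(marker = e$marker, metal = e$metal, category = e$category,
               stringsAsFactors = FALSE)
  })
  panel_definition(do.call(rbind, rows), version = version)
}

#' Write a panel definition to YAML
#'
#' @param panel a `senocyto_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "senocyto_panel"))
  out <- list(
    version = panel$version,
    channels = lapply(seq_len(nrow(panel$channels)), function(i) {
      as.list(panel$channels[i, c("marker", "metal", "category")])
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Marker names in a panel, optionally filtered by category
#'
#' @param panel a `senocyto_panel`.
#' @param category optional character vector of categories to keep.
#' @return Character vector of marker names in panel order.
#' @export
panel_markers <- function(panel, category = NULL) {
  ch <- panel$channels
  if (!is.null(category)) ch <- ch[ch$category %in% category, , drop = FALSE]
  ch$marker
}

#' Senescence-phenotyping marker set
#'
#' The functional panel used for senescent-cell profiling and archetype
#' clustering: senescence, SASP, DNA-damage, anti-apoptosis and proliferation
#' channels.
#'
#' @param panel a `senocyto_panel`.
#' @return Character vector of marker names.
#' @export
senescence_panel_markers <- function(panel) {
  panel_markers(panel, c("senescence", "sasp", "dna_damage",
                         "anti_apoptosis", "proliferation"))
}

# Column index of a marker in a panel (case/alias-insensitive); error when
# absent unless required = FALSE.
.marker_col <- function(panel, marker, required = TRUE) {
  idx <- match(.canon_marker(.resolve_marker_name(marker)),
               .canon_marker(panel$channels$marker))
  if (required && any(is.na(idx))) {
    stop("marker not in panel: ", paste(marker[is.na(idx)], collapse = ", "))
  }
  idx
}

# Single instrument channel index by category; error names the channel when
# required and absent.
.instrument_col <- function(panel, category, required = TRUE) {
  idx <- which(panel$channels$category == category)
  if (length(idx) == 0L) {
    if (required) stop("panel has no ", category, " channel")
    return(integer(0))
  }
  idx
}

#' Read a cohort design table
#'
#' Tab-separated file with header columns `sample_id`, `age_group`,
#' `treatment`, `genotype`, `file_path`. `ko_control` genotype rows are
#' reserved for threshold derivation and are excluded from cohort-level
#' statistics downstream.
#'
#' @param path TSV file path.
#' @return data.frame of class `senocyto_design` with an added `group`
#'   column (`young`, `old`, `old_senolytic`, or `ko_control`).
#' @export
read_cohort_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  cohort_design(d)
}

#' Construct / validate a cohort design
#'
#' @param d data.frame with columns `sample_id`, `age_group`, `treatment`,
#'   `genotype` and optionally `file_path`.
#' @return Validated design with derived `group` column.
#' @export
cohort_design <- function(d) {
  need <- c("sample_id", "age_group", "treatment", "genotype")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("design lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample_id in design: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  }
  stopifnot(all(d$age_group %in% c("young", "old")),
            all(d$treatment %in% c("none", "vehicle", "senolytic")),
            all(d$genotype %in% c("wildtype", "ko_control")))
  if (is.null(d$file_path)) d$file_path <- NA_character_
  d$group <- ifelse(
    d$genotype == "ko_control", "ko_control",
    ifelse(d$age_group == "young", "young",
           ifelse(d$treatment == "senolytic", "old_senolytic", "old"))
  )
  class(d) <- c("senocyto_design", "data.frame")
  d
}

#' Write a cohort design table
#'
#' @param design a cohort design data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_design <- function(design, path) {
  cols <- intersect(c("sample_id", "age_group", "treatment", "genotype",
                      "file_path"), names(design))
  utils::write.table(design[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default CyTOF antibody panel
#'
#' The shipped bone/marrow mesenchymal senescence panel: 19 identity markers
#' (stromal, perivascular, osteolineage and adipocyte markers), the
#' senescence module (CENP-B, p21, p16, p53), DNA-damage (yH2A-X, pATM),
#' anti-apoptosis (BCL-2), proliferation (Ki67), eight SASP factors, the
#' FLAG transgene reporter, CD45 plus a pooled lineage cocktail channel for
#' negative selection, and the four instrument channels (DNA intercalator,
#' cisplatin viability, calibration beads, event length).
#'
#' @return A `senocyto_panel`.
#' @export
default_panel <- function() {
  path <- system.file("extdata", "config", "default_panel.yaml",
                      package = "senocyto")
  if (!nzchar(path)) stop("default panel config not installed")
  load_panel(path)
}
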