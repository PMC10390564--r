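# Event matrices: per-sample events x channels intensity tables with
# instrument channels and optional per-event simulation truth.

#' Construct an event matrix
#'
#' @param values numeric matrix, events x channels; columns must match the
#'   panel's channels (by position or by name resolvable to panel markers).
#' @param panel a `senocyto_panel` describing the columns.
#' @param sample_id sample identifier.
#' @param transformed logical; `TRUE` iff the arcsinh transform has been
#'   applied (it is applied at most once).
#' @param truth optional data.frame of per-event ground-truth labels
#'   (simulated data only), one row per event.
#' @return An object of class `senocyto_events`.
#' @export
event_matrix <- function(values, panel, sample_id = "sample",
                         transformed = FALSE, truth = NULL) {
  stopifnot(inherits(panel, "senocyto_panel"))
  values <- as.matrix(values)
  if (ncol(values) != nrow(panel$channels)) {
    stop("column count (", ncol(values), ") does not match panel channel count (",
         nrow(panel$channels), ")")
  }
  if (nrow(values) > 0 && anyNA(values)) stop("event matrix contains missing values")
  storage.mode(values) <- "double"
  colnames(values) <- panel$channels$marker
  if (!is.null(truth)) {
    truth <- as.data.frame(truth)
    if (nrow(truth) != nrow(values)) {
      stop("truth table row count must equal event count")
    }
  }
  structure(
    list(values = values, panel = panel, sample_id = sample_id,
         transformed = isTRUE(transformed), truth = truth),
    class = "senocyto_events"
  )
}

#' @export
print.senocyto_events <- function(x, ...) {
  cat("senocyto events: sample '", x$sample_id, "', ", nrow(x$values),
      " events x ", ncol(x$values), " channels",
      if (x$transformed) " (arcsinh)" else " (raw)",
      if (!is.null(x$truth)) ", with truth labels" else "", "\n", sep = "")
  invisible(x)
}

#' Number of events
#' @param matrix a `senocyto_events`.
#' @return Integer event count.
#' @export
n_events <- function(matrix) nrow(matrix$values)

# Row-subset an event matrix (keeps truth aligned).
.subset_events <- function(matrix, keep) {
  matrix$values <- matrix$values[keep, , drop = FALSE]
  if (!is.null(matrix$truth)) {
    matrix$truth <- matrix$truth[keep, , drop = FALSE]
    rownames(matrix$truth) <- NULL
  }
  matrix
}

# Intensity vector for one marker.
.marker_values <- function(matrix, marker) {
  matrix$values[, .marker_col(matrix$panel, marker)]
}

#' Read events from file
#'
#' Dispatches on content: FCS files (magic bytes `FCS3.0`/`FCS3.1`) are read
#' with the built-in single-segment FCS reader; anything else is read as a
#' delimited table (TSV/CSV, header row of marker or metal names). File
#' channels are resolved to the panel case-insensitively by marker name or
#' metal tag; unmapped file columns are dropped with a warning, and negative
#' intensities are clamped to zero with a message reporting the count. A
#' truth sidecar written by [write_events()] (`<path>.truth.tsv`) is picked
#' up automatically.
#'
#' @param path input file.
#' @param panel a `senocyto_panel`.
#' @param sample_id sample identifier; defaults to the file stem.
#' @return A `senocyto_events` on the raw scale (`transformed = FALSE`).
#' @export
read_events <- function(path, panel, sample_id = NULL) {
  if (!file.exists(path)) stop("event file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fcs|tsv|csv|txt)$", "", basename(path),
                     ignore.case = TRUE)
  }
  magic <- readBin(path, "raw", n = 6L)
  is_fcs <- identical(rawToChar(magic), "FCS3.0") ||
    identical(rawToChar(magic), "FCS3.1")
  if (is_fcs) {
    parsed <- .read_fcs(path)
    values <- parsed$data
    file_names <- ifelse(nzchar(parsed$marker), parsed$marker, parsed$metal)
    file_metals <- parsed$metal
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    values <- as.matrix(tab)
    storage.mode(values) <- "double"
    file_names <- colnames(values)
    file_metals <- rep(NA_character_, ncol(values))
  }

  # Resolve file columns to panel channels by marker name, then metal tag.
  canon_panel <- .canon_marker(panel$channels$marker)
  idx <- match(.canon_marker(.resolve_marker_name(file_names)), canon_panel)
  metal_idx <- match(tolower(file_metals), tolower(panel$channels$metal))
  idx[is.na(idx)] <- metal_idx[is.na(idx)]
  if (all(is.na(idx)) && ncol(values) > 0) {
    stop("format error: no file channels resolvable to the panel")
  }
  dropped <- file_names[is.na(idx)]
  if (length(dropped)) {
    warning("dropping unmapped file column(s): ",
            paste(dropped, collapse = ", "))
  }
  n_panel <- nrow(panel$channels)
  out <- matrix(0, nrow = nrow(values), ncol = n_panel)
  present <- !is.na(idx)
  out[, idx[present]] <- values[, present, drop = FALSE]
  missing_ch <- setdiff(seq_len(n_panel), idx[present])
  if (length(missing_ch) && nrow(values) > 0) {
    warning("panel channel(s) absent from file, filled with 0: ",
            paste(panel$channels$marker[missing_ch], collapse = ", "))
  }
  n_neg <- sum(out < 0)
  if (n_neg > 0) {
    message("clamped ", n_neg, " negative intensities to 0")
    out[out < 0] <- 0
  }

  truth <- NULL
  sidecar <- paste0(path, ".truth.tsv")
  if (file.exists(sidecar)) {
    truth <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    for (fl in intersect(names(truth),
                         c("p16_true", "p21_true", "ki67_true", "bcl2_true",
                           "p16kb_true", "p21kb_true"))) {
      truth[[fl]] <- as.logical(truth[[fl]])
    }
  }
  event_matrix(out, panel, sample_id = sample_id, truth = truth)
}

#' Write events to file
#'
#' TSV output has one header row of marker names and one row per event; FCS
#' output is a single-dataset FCS 3.1 file with float data, `$PnN` = metal
#' tag and `$PnS` = marker name. Truth labels, when present, go to a sidecar
#' `<path>.truth.tsv` — never into intensity channels.
#'
#' @param matrix a `senocyto_events`.
#' @param path output file.
#' @param format `"tsv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(matrix, path, format = c("tsv", "fcs")) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "senocyto_events"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("I/O error: directory does not exist: ", dir)
  if (format == "tsv") {
    tab <- as.data.frame(matrix$values)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    .write_fcs(matrix$values, metals = matrix$panel$channels$metal,
               markers = matrix$panel$channels$marker, path = path)
  }
  if (!is.null(matrix$truth)) {
    utils::write.table(matrix$truth, paste0(path, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal FCS 3.1 reader/writer: single data segment, list-mode float
# (DATATYPE F) or integer (DATATYPE I) data, little- or big-endian.
# $PnN carries the metal tag, $PnS the marker name. Spillover, multi-dataset
# files and analysis segments are out of scope.

.read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", n = 58L))
  txt_start <- as.integer(substr(header, 11, 18))
  txt_end <- as.integer(substr(header, 19, 26))
  data_start <- as.integer(substr(header, 27, 34))
  data_end <- as.integer(substr(header, 35, 42))

  seek(con, txt_start)
  txt <- rawToChar(readBin(con, "raw", n = txt_end - txt_start + 1L))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(as.list(vals), toupper(trimws(keys)))

  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  byteord <- kw[["$BYTEORD"]]
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"
  if (data_start == 0 && !is.null(kw[["$BEGINDATA"]])) {
    data_start <- as.integer(kw[["$BEGINDATA"]])
    data_end <- as.integer(kw[["$ENDDATA"]])
  }
  seek(con, data_start)
  n_values <- n_par * n_tot
  if (dtype == "F") {
    raw_vals <- readBin(con, "numeric", n = n_values, size = 4L,
                        endian = endian)
  } else if (dtype == "I") {
    bits <- as.integer(kw[["$P1B"]])
    raw_vals <- readBin(con, "integer", n = n_values, size = bits %/% 8L,
                        endian = endian, signed = FALSE)
  } else {
    stop("unsupported FCS $DATATYPE: ", dtype)
  }
  data <- matrix(raw_vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  metal <- vapply(seq_len(n_par), function(i) {
    v <- kw[[paste0("$P", i, "N")]]
    if (is.null(v)) "" else v
  }, character(1))
  marker <- vapply(seq_len(n_par), function(i) {
    v <- kw[[paste0("$P", i, "S")]]
    if (is.null(v)) "" else v
  }, character(1))
  list(data = data, metal = metal, marker = marker, keywords = kw)
}

.write_fcs <- function(values, metals, markers, path) {
  n_tot <- nrow(values)
  n_par <- ncol(values)
  delim <- "/"
  kw <- c(
    "$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot),
    "$NEXTDATA" = "0"
  )
  for (i in seq_len(n_par)) {
    rng <- max(1, ceiling(max(values[, i], 0, na.rm = TRUE)) + 1)
    kw[paste0("$P", i, "N")] <- metals[i]
    kw[paste0("$P", i, "S")] <- markers[i]
    kw[paste0("$P", i, "B")] <- "32"
    kw[paste0("$P", i, "E")] <- "0,0"
    kw[paste0("$P", i, "R")] <- as.character(rng)
  }
  # Two-pass offset fix-up: write placeholder offsets sized generously.
  build_text <- function(begin_data, end_data) {
    kws <- c(kw, "$BEGINDATA" = sprintf("%d", begin_data),
             "$ENDDATA" = sprintf("%d", end_data),
             "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
             "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0")
    paste0(delim, paste0(names(kws), delim, unname(kws), delim,
                         collapse = ""))
  }
  header_len <- 58L
  txt0 <- build_text(999999999, 999999999)
  txt_start <- header_len
  txt_end <- txt_start + nchar(txt0, type = "bytes") - 1L
  data_start <- txt_end + 1L
  data_len <- n_tot * n_par * 4L
  data_end <- data_start + max(data_len - 1L, 0L)
  # Rebuild text with true offsets, padding to keep its length fixed.
  txt <- build_text(data_start, data_end)
  pad <- nchar(txt0, type = "bytes") - nchar(txt, type = "bytes")
  txt <- paste0(txt, strrep(" ", pad))

  hdr_field <- function(x) formatC(x, width = 8, flag = " ")
  use_hdr_data <- data_end <= 99999999
  header <- paste0(
    "FCS3.1    ",
    hdr_field(txt_start), hdr_field(txt_end),
    hdr_field(if (use_hdr_data) data_start else 0),
    hdr_field(if (use_hdr_data) data_end else 0),
    hdr_field(0), hdr_field(0)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}
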