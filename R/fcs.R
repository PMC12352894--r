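## Minimal FCS 3.0 reader/writer (float32 list-mode data segment) and the
## tabular fall-back reader. Marker names are carried in $PnS (stain) with
## $PnN as the short name.

#' Write events to an FCS 3.0 file
#'
#' One file per sample per panel; float32 list-mode data, little-endian,
#' marker names in `$PnS`.
#'
#' @param values cells x markers numeric matrix (raw scale).
#' @param path output file.
#' @param sample_id,panel stored as `$SRC` / `CYTOSTRAT_PANEL` keywords.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(values, path, sample_id = "sample", panel = "panel") {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  n <- nrow(values); p <- ncol(values)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$TOT", as.character(n), "$PAR", as.character(p),
          "$NEXTDATA", "0", "$SRC", sample_id, "CYTOSTRAT_PANEL", panel)
  for (j in seq_len(p)) {
    kw <- c(kw,
            sprintf("$P%dN", j), sprintf("ch%02d", j),
            sprintf("$P%dS", j), colnames(values)[j],
            sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), "262144")
  }
  ## assemble TEXT with placeholder offsets, then fix their width
  build_text <- function(begin_data, end_data) {
    all_kw <- c("$BEGINDATA", sprintf("%010d", begin_data),
                "$ENDDATA", sprintf("%010d", end_data), kw)
    paste0("|", paste(all_kw, collapse = "|"), "|")
  }
  header_len <- 58L
  text0 <- build_text(0, 0)
  text_begin <- header_len
  text_end <- text_begin + nchar(text0, type = "bytes") - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * n * p - 1L
  text <- build_text(data_begin, data_end)
  stopifnot(nchar(text, type = "bytes") == nchar(text0, type = "bytes"))
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end, data_begin, data_end, 0L, 0L)
  stopifnot(nchar(header, type = "bytes") == header_len)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FCS 3.x file
#'
#' Parses the TEXT segment, prefers `$PnS` over `$PnN` for marker naming,
#' and reads the float32/float64 list-mode data segment. Events are
#' returned on the raw scale.
#'
#' @param path FCS file.
#' @return list: `values` (cells x markers), `keywords` (named character).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (substr(header, 1, 3) != "FCS") stop("not an FCS file: ", path)
  offs <- suppressWarnings(as.integer(trimws(
    substring(header, seq(11, 51, by = 8), seq(18, 58, by = 8)))))
  if (anyNA(offs[1:2])) stop("truncated FCS header: ", path)
  seek(con, offs[1])
  text <- readChar(con, offs[2] - offs[1] + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2) stop("empty TEXT segment: ", path)
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- stats::setNames(vals, toupper(keys))
  n <- as.integer(kw["$TOT"]); p <- as.integer(kw["$PAR"])
  if (anyNA(c(n, p))) stop("missing $TOT/$PAR: ", path)
  data_begin <- as.integer(kw["$BEGINDATA"])
  if (is.na(data_begin) || data_begin == 0L) data_begin <- offs[3]
  dtype <- toupper(kw["$DATATYPE"])
  size <- switch(dtype, F = 4L, D = 8L,
                 stop("unsupported $DATATYPE: ", dtype))
  endian <- if (startsWith(kw["$BYTEORD"], "1")) "little" else "big"
  seek(con, data_begin)
  raw_vals <- readBin(con, "numeric", n * p, size = size, endian = endian)
  if (length(raw_vals) < n * p) stop("truncated data segment: ", path)
  mk <- vapply(seq_len(p), function(j) {
    s <- kw[sprintf("$P%dS", j)]
    if (!is.na(s) && nzchar(s)) s else kw[sprintf("$P%dN", j)]
  }, "")
  values <- matrix(raw_vals, n, p, byrow = TRUE,
                   dimnames = list(NULL, mk))
  list(values = values, keywords = kw)
}

#' Read per-sample events from FCS or tabular files
#'
#' The tabular format is CSV with one `marker:<name>` column per marker.
#' Marker names are checked against the panel configuration; unknown
#' markers are rejected by name. A zero-event file yields an empty matrix
#' (downstream QC removes the sample).
#'
#' @param path file path.
#' @param format `"fcs"` or `"tabular"`.
#' @param panel optional panel configuration (see [default_panels()]);
#'   when given, marker names must match it exactly.
#' @return list: `values` (cells x markers raw-scale matrix), `scale`
#'   (`"raw"`), plus `keywords` for FCS input.
#' @export
read_events <- function(path, format = c("fcs", "tabular"), panel = NULL) {
  format <- match.arg(format)
  if (format == "fcs") {
    out <- read_fcs(path)
    values <- out$values
  } else {
    tab <- utils::read.csv(path, check.names = FALSE)
    mk_cols <- grep("^marker:", names(tab))
    if (!length(mk_cols)) stop("no marker:<name> columns in ", path)
    values <- as.matrix(tab[, mk_cols, drop = FALSE])
    colnames(values) <- sub("^marker:", "", names(tab)[mk_cols])
    out <- list()
  }
  if (!is.null(panel)) {
    unknown <- setdiff(colnames(values), panel$markers)
    if (length(unknown)) stop("unknown markers: ",
                              paste(unknown, collapse = ", "))
    missing <- setdiff(panel$markers, colnames(values))
    if (length(missing)) stop("missing markers: ",
                              paste(missing, collapse = ", "))
    values <- values[, panel$markers, drop = FALSE]
  }
  c(list(values = values, scale = "raw"), out["keywords"])
}

#' Write a cohort's events as one FCS file per sample per panel
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed); metadata and design
#'   seeds are written alongside as CSV.
#' @return character vector of written FCS paths, invisibly.
#' @export
write_cohort_fcs <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (pn in names(cohort$events)) {
    e <- cohort$events[[pn]]
    for (s in levels(droplevels(e$sample))) {
      v <- e$values[e$sample == s, , drop = FALSE]
      f <- file.path(dir, sprintf("%s_%s.fcs", s, pn))
      write_fcs(v, f, sample_id = s, panel = pn)
      paths <- c(paths, f)
    }
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(paths)
}
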