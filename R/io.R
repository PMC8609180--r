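#' Read a multichannel recording from disk
#'
#' Two dialects are supported.  *Delimited text* (`.tsv`, `.txt`, `.csv`):
#' header lines `# fs=<Hz>`, `# labels=<comma-separated>`,
#' `# units=<comma-separated>` (and optionally `# t0=<s>`) followed by one
#' column per channel.  *HDF5* (`.h5`, `.hdf5`): a `/data` dataset
#' (channels x time) with attributes `fs`, `labels`, `units`, `t0`.  HDF5
#' round-trips are bit-exact; delimited round-trips preserve the full
#' printed precision.
#'
#' @param path input file.
#' @param dialect `"auto"` (by extension), `"delimited"` or `"hdf5"`.
#' @return a [recording].
#' @export
read_recording <- function(path, dialect = c("auto", "delimited", "hdf5")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      h5 = , hdf5 = "hdf5",
      tsv = , txt = , csv = , dat = "delimited",
      abort(sprintf("unsupported dialect: extension '.%s'", ext))
    )
  }
  if (dialect == "hdf5") {
    raw <- .Call(c_h5_read_recording, path.expand(path))
    labels <- raw$labels %||% paste0("ch", seq_len(nrow(raw$data)))
    units <- raw$units %||% rep("uV", nrow(raw$data))
    return(recording(raw$data, raw$fs, units = units,
      channel_labels = labels, t0 = raw$t0))
  }
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(sprintf("^#\\s*%s=", key), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    sub(sprintf("^#\\s*%s=", key), "", m[1])
  }
  fs <- get_field("fs")
  if (is.null(fs)) abort("malformed header: missing '# fs=' line")
  fs <- as.numeric(fs)
  if (is.na(fs)) abort("malformed header: fs is not numeric")
  labels <- get_field("labels")
  units <- get_field("units")
  t0 <- as.numeric(get_field("t0") %||% "0")
  dat <- utils::read.table(path, header = FALSE, sep = "\t",
    comment.char = "#", colClasses = "numeric", fill = TRUE)
  if (anyNA(dat)) abort("inconsistent channel lengths")
  m <- unname(t(as.matrix(dat)))
  labels <- if (!is.null(labels)) strsplit(labels, ",")[[1]] else NULL
  units <- if (!is.null(units)) strsplit(units, ",")[[1]] else "uV"
  recording(m, fs, units = units, channel_labels = labels, t0 = t0)
}

#' Write a recording to disk
#'
#' @param rec a [recording].
#' @param path output file; the extension selects the dialect unless given
#'   explicitly.
#' @param dialect see [read_recording()].
#' @param digits significant digits for the delimited dialect.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path,
                            dialect = c("auto", "delimited", "hdf5"),
                            digits = 10) {
  stopifnot(inherits(rec, "recording"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      h5 = , hdf5 = "hdf5",
      tsv = , txt = , csv = , dat = "delimited",
      abort(sprintf("unsupported dialect: extension '.%s'", ext))
    )
  }
  if (dialect == "hdf5") {
    .Call(c_h5_write_recording, path.expand(path), rec$data,
      as.numeric(rec$fs), rec$channel_labels, rec$units, as.numeric(rec$t0))
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%.10g", rec$fs),
    sprintf("# labels=%s", paste(rec$channel_labels, collapse = ",")),
    sprintf("# units=%s", paste(rec$units, collapse = ",")),
    sprintf("# t0=%.10g", rec$t0)
  ), con)
  utils::write.table(
    format(t(rec$data), digits = digits, scientific = TRUE, trim = TRUE),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; floating values keep full precision so
#' a read-back reproduces the values.  An empty table produces a
#' header-only file.
#'
#' @param table a data frame / tibble with unique column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table))) abort("column names must be unique")
  table <- dplyr::select(table, dplyr::where(\(x) !is.list(x)))
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read a result table written by [write_table()]
#' @param path TSV path.
#' @return a tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
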