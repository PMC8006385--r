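# Delimited-table readers: count matrices, taxonomy, metadata.

# Split lines on the delimiter, checking rectangularity; returns list of
# character vectors. Line numbers refer to the file, header = line 1.
split_table_lines <- function(path, delimiter) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop_parse(sprintf("%s: need a header plus at least one data row", path))
  }
  strsplit(lines, delimiter, fixed = TRUE)
}

#' Read a delimited count/OTU/ASV table
#'
#' Expects a rectangular delimited text file with a header row and a
#' leading row-label column. Counts must be integral; a float within 1e-9
#' of a whole number (e.g. `"5.0"`) is accepted and cast, anything else is
#' rejected with its line number.
#'
#' @param path Path to the file.
#' @param orientation `"features_in_rows"` (default: genomes/OTUs in rows,
#'   samples in columns) or `"samples_in_rows"` (transposed input).
#' @param delimiter Field separator, default tab.
#' @return Numeric matrix of integral counts, features x samples.
#' @export
readCountTable <- function(path,
                           orientation = c("features_in_rows",
                                           "samples_in_rows"),
                           delimiter = "\t") {
  orientation <- match.arg(orientation)
  fields <- split_table_lines(path, delimiter)
  header <- fields[[1L]]
  body <- fields[-1L]
  # A header may or may not name the row-label column; accept both widths.
  ncol_body <- lengths(body)
  expect <- unique(ncol_body)
  if (length(expect) != 1L) {
    bad <- which(ncol_body != ncol_body[1L])[1L] + 1L
    stop_parse(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                       path, bad, ncol_body[bad - 1L], ncol_body[1L]))
  }
  col_ids <- if (length(header) == expect) header[-1L] else header
  if (length(col_ids) != expect - 1L) {
    stop_parse(sprintf("%s: header has %d fields but rows have %d",
                       path, length(header), expect))
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(row_ids)) {
    dup <- unique(row_ids[duplicated(row_ids)])[1L]
    stop_parse(sprintf("%s: duplicate row label '%s' at line %d", path, dup,
                       which(row_ids == dup)[2L] + 1L))
  }
  if (anyDuplicated(col_ids)) {
    stop_parse(sprintf("%s: duplicate column label '%s'", path,
                       unique(col_ids[duplicated(col_ids)])[1L]))
  }
  m <- matrix(NA_real_, length(row_ids), length(col_ids),
              dimnames = list(row_ids, col_ids))
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      stop_parse(sprintf("%s: non-numeric cell '%s' at line %d, column '%s'",
                         path, body[[i]][j + 1L], i + 1L, col_ids[j]))
    }
    dev <- abs(vals - round(vals))
    if (any(dev > 1e-9)) {
      j <- which(dev > 1e-9)[1L]
      stop_parse(sprintf(
        "%s: non-integral count '%s' at line %d, column '%s'",
        path, body[[i]][j + 1L], i + 1L, col_ids[j]))
    }
    m[i, ] <- round(vals)
  }
  if (any(m < 0)) {
    stop_parse(sprintf("%s: negative counts are not allowed", path))
  }
  if (orientation == "samples_in_rows") m <- t(m)
  m
}

#' Read a taxonomy table
#'
#' Header names must be a subset of [taxonomyRanks()] (case-insensitive);
#' columns are reordered to canonical rank order. Blank or missing entries
#' become [unclassifiedMarker()].
#'
#' @param path Path to a delimited file, feature ids in the first column.
#' @param delimiter Field separator, default tab.
#' @return Data frame with rank columns in canonical order, feature ids as
#'   rownames.
#' @export
readTaxonomyTable <- function(path, delimiter = "\t") {
  fields <- split_table_lines(path, delimiter)
  header <- fields[[1L]]
  body <- fields[-1L]
  width <- max(lengths(fields))
  col_ids <- if (length(header) == width) header[-1L] else header
  recognized <- tolower(col_ids) %in% taxonomyRanks()
  if (!any(recognized)) {
    stop_parse(sprintf("%s: no recognized taxonomy rank columns (have: %s)",
                       path, paste(col_ids, collapse = ", ")))
  }
  if (!all(recognized)) {
    stop_parse(sprintf("%s: unknown rank column(s): %s", path,
                       paste(col_ids[!recognized], collapse = ", ")))
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(row_ids)) {
    stop_parse(sprintf("%s: duplicate feature id '%s'", path,
                       unique(row_ids[duplicated(row_ids)])[1L]))
  }
  # Pad short rows (trailing blanks collapse under strsplit) with "".
  tab <- t(vapply(body, function(x) {
    v <- x[-1L]
    length(v) <- length(col_ids)
    v
  }, character(length(col_ids))))
  tax <- as.data.frame(tab, stringsAsFactors = FALSE)
  colnames(tax) <- tolower(col_ids)
  rownames(tax) <- row_ids
  normalize_taxonomy(tax)
}

#' Read a sample-metadata table
#'
#' First column holds sample ids; remaining columns become covariates.
#' Columns that parse entirely as numbers are stored numeric.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field separator, default tab.
#' @return Data frame with sample ids as rownames.
#' @export
readMetadataTable <- function(path, delimiter = "\t") {
  md <- utils::read.delim(path, sep = delimiter, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(rownames(md))) {
    stop_parse(sprintf("%s: duplicate sample ids", path))
  }
  md
}
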