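# PathoScope-style per-sample report import.

#' Combine PathoScope per-sample reports into one experiment
#'
#' Each report is a tab-delimited table for a single sample whose genome
#' identifiers embed an NCBI taxid as `ti|<taxid>`. The union of taxa
#' across files forms the feature set; taxa absent from a report get count
#' zero. The sample id is the filename stem. Taxonomy is left absent (no
#' network lookup is performed); supply a taxonomy table separately if
#' level aggregation is needed.
#'
#' The column defaults follow the PathoScope report schema; both are
#' overridable. Duplicate taxon rows within one report are summed with a
#' warning.
#'
#' @param paths Character vector of report file paths (>= 1).
#' @param id_column Name of the genome-identifier column.
#' @param count_column Name of the read-count column.
#' @param metadata Optional sample metadata data frame (rownames = file
#'   stems); default is an empty covariate table.
#' @return A [MicrobiomeExperiment-class], taxonomy absent.
#' @export
readPathoscopeReports <- function(paths,
                                  id_column = "Genome",
                                  count_column = "Final Best Hit Read Numbers",
                                  metadata = NULL) {
  if (length(paths) < 1L) stop_validation("need at least one report file")
  stems <- sub("\\.[^.]*$", "", basename(paths))
  if (anyDuplicated(stems)) {
    stop_validation("report filenames must have unique stems")
  }
  per_sample <- lapply(seq_along(paths), function(i) {
    p <- paths[i]
    if (!file.exists(p)) stop_parse(sprintf("file not found: %s", p))
    tab <- utils::read.delim(p, check.names = FALSE,
                             stringsAsFactors = FALSE)
    miss <- setdiff(c(id_column, count_column), colnames(tab))
    if (length(miss)) {
      stop_parse(sprintf("%s: missing column(s): %s", p,
                         paste(miss, collapse = ", ")))
    }
    ids <- as.character(tab[[id_column]])
    if (any(!nzchar(ids))) stop_parse(sprintf("%s: empty genome id", p))
    cts <- as_integral(as.numeric(tab[[count_column]]),
                       what = sprintf("%s counts", p))
    if (any(cts < 0)) stop_parse(sprintf("%s: negative read count", p))
    # Prefer the embedded taxid as the feature key when present.
    ti <- regmatches(ids, regexpr("ti\\|\\d+", ids))
    key <- ids
    has_ti <- grepl("ti\\|\\d+", ids)
    key[has_ti] <- regmatches(ids, regexpr("ti\\|\\d+", ids))
    if (anyDuplicated(key)) {
      warning(sprintf("%s: duplicate taxon rows summed", p), call. = FALSE)
      agg <- rowsum(cts, key, reorder = FALSE)
      key <- rownames(agg)
      cts <- as.numeric(agg)
    }
    stats::setNames(cts, key)
  })
  features <- sort(unique(unlist(lapply(per_sample, names))))
  m <- matrix(0, length(features), length(paths),
              dimnames = list(features, stems))
  for (i in seq_along(per_sample)) {
    m[names(per_sample[[i]]), i] <- per_sample[[i]]
  }
  if (is.null(metadata)) {
    metadata <- data.frame(row.names = stems)
  }
  MicrobiomeExperiment(m, taxonomy = NULL, metadata = metadata)
}
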