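# Construction, accessors and coordinated subsetting of the container.

#' Construct a MicrobiomeExperiment
#'
#' Builds and validates the coordinated triple of raw counts, optional
#' taxonomy and sample metadata. Taxonomy and metadata rows are reordered to
#' match the row/column labels of `counts`, so any input row order is
#' accepted as long as the identifier sets match.
#'
#' @param counts Numeric matrix of raw read counts, features in rows and
#'   samples in columns, with unique non-empty dimnames. Values must be
#'   non-negative and integral (a float within 1e-9 of a whole number is
#'   accepted and cast).
#' @param taxonomy Optional data frame of taxonomic assignments, one row per
#'   feature (rownames = feature ids), columns drawn from [taxonomyRanks()]
#'   (any case). Blank or `NA` entries become [unclassifiedMarker()].
#'   `NULL` disables taxonomy-level aggregation.
#' @param metadata Data frame of per-sample covariates, rownames = sample
#'   ids. Must cover every sample in `counts`.
#' @return A validated [MicrobiomeExperiment-class].
#' @export
#' @examples
#' cts <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
#'               dimnames = list(c("taxA", "taxB"), c("S1", "S2")))
#' md <- data.frame(group = c("a", "b"), row.names = c("S1", "S2"))
#' me <- MicrobiomeExperiment(cts, metadata = md)
#' me
MicrobiomeExperiment <- function(counts, taxonomy = NULL, metadata) {
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts))) {
    stop_validation("counts must be a matrix with row and column labels")
  }
  fid <- rownames(counts)
  sid <- colnames(counts)
  if (anyDuplicated(fid)) {
    stop_validation(sprintf("duplicate feature ids: %s",
                            paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  }
  if (anyDuplicated(sid)) {
    stop_validation(sprintf("duplicate sample ids: %s",
                            paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  counts[] <- as_integral(as.numeric(counts))
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop_validation(sprintf("negative count for feature '%s', sample '%s'",
                            fid[bad[1L]], sid[bad[2L]]))
  }

  if (!is.data.frame(metadata) && !is(metadata, "DataFrame")) {
    stop_validation("metadata must be a data frame with sample rownames")
  }
  metadata <- as.data.frame(metadata)
  missing_s <- setdiff(sid, rownames(metadata))
  if (length(missing_s)) {
    stop_validation(sprintf("metadata is missing sample(s): %s",
                            paste(missing_s, collapse = ", ")))
  }
  metadata <- metadata[sid, , drop = FALSE]

  rd <- S4Vectors::DataFrame(row.names = fid)
  if (!is.null(taxonomy)) {
    tax <- normalize_taxonomy(taxonomy)
    missing_f <- setdiff(fid, rownames(tax))
    if (length(missing_f)) {
      stop_validation(sprintf("taxonomy is missing feature(s): %s",
                              paste(missing_f, collapse = ", ")))
    }
    rd <- S4Vectors::DataFrame(tax[fid, , drop = FALSE])
    rownames(rd) <- fid
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = rd,
    colData = S4Vectors::DataFrame(metadata)
  )
  new("MicrobiomeExperiment", se)
}

# Coerce a taxonomy table to canonical form: recognised rank columns
# (case-insensitive), canonical order, character entries, blanks/NA ->
# "unclassified".
normalize_taxonomy <- function(taxonomy) {
  taxonomy <- as.data.frame(taxonomy)
  if (is.null(rownames(taxonomy))) {
    stop_validation("taxonomy must have feature ids as rownames")
  }
  nm <- tolower(colnames(taxonomy))
  known <- taxonomyRanks()
  unknown <- setdiff(nm, known)
  if (length(unknown)) {
    stop_validation(sprintf("unknown taxonomy rank column(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  if (!length(nm)) stop_validation("taxonomy has no rank columns")
  colnames(taxonomy) <- nm
  taxonomy <- taxonomy[, known[known %in% nm], drop = FALSE]
  for (r in colnames(taxonomy)) {
    v <- as.character(taxonomy[[r]])
    v[is.na(v) | trimws(v) == ""] <- unclassifiedMarker()
    taxonomy[[r]] <- v
  }
  taxonomy
}

# Accessors ---------------------------------------------------------------

#' Access the parts of a MicrobiomeExperiment
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @return `meCounts()`: the raw count matrix, exactly as stored.
#'   `taxonomyTable()`: data frame of taxonomy (or `NULL` if absent).
#'   `sampleData()`: data frame of sample covariates.
#'   `featureIds()`, `sampleIds()`: identifier vectors.
#' @export
meCounts <- function(exp) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  SummarizedExperiment::assay(exp, "counts")
}

#' @rdname meCounts
#' @export
taxonomyTable <- function(exp) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  rd <- SummarizedExperiment::rowData(exp)
  if (ncol(rd) == 0L) return(NULL)
  as.data.frame(rd)
}

#' @rdname meCounts
#' @export
sampleData <- function(exp) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  as.data.frame(SummarizedExperiment::colData(exp))
}

#' @rdname meCounts
#' @export
featureIds <- function(exp) rownames(exp)

#' @rdname meCounts
#' @export
sampleIds <- function(exp) colnames(exp)

setMethod("show", "MicrobiomeExperiment", function(object) {
  cat(sprintf("MicrobiomeExperiment: %d features x %d samples\n",
              nrow(object), ncol(object)))
  tax <- SummarizedExperiment::rowData(object)
  if (ncol(tax)) {
    cat("  taxonomy ranks:", paste(colnames(tax), collapse = ", "), "\n")
  } else {
    cat("  taxonomy: absent\n")
  }
  md <- SummarizedExperiment::colData(object)
  if (ncol(md)) {
    cat("  covariates:", paste(colnames(md), collapse = ", "), "\n")
  }
})

# Subsetting --------------------------------------------------------------

pick_ids <- function(have, ids, mode, what) {
  mode <- match.arg(mode, c("keep", "discard"))
  unknown <- setdiff(ids, have)
  if (length(unknown)) {
    stop_validation(sprintf("unknown %s id(s): %s", what,
                            paste(unknown, collapse = ", ")))
  }
  kept <- if (mode == "keep") have[have %in% ids] else setdiff(have, ids)
  if (!length(kept)) {
    stop_validation(sprintf(
      "empty selection: no %ss would remain after '%s'", what, mode))
  }
  kept
}

#' Isolate or discard samples / features, keeping the tables aligned
#'
#' Coordinated subsetting: counts, taxonomy and metadata are subset
#' together so the container invariants hold on the result. An empty
#' selection is an error (downstream statistics are undefined on zero
#' samples or features).
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @param ids Character vector of sample (or feature) ids; must all exist.
#' @param mode `"keep"` to retain exactly `ids`, `"discard"` to drop them.
#' @return A [MicrobiomeExperiment-class] with the selected samples
#'   (features), original relative order preserved.
#' @export
#' @examples
#' cts <- matrix(1:6, 2, 3, dimnames = list(c("f1", "f2"), c("a", "b", "c")))
#' md <- data.frame(g = c("x", "x", "y"), row.names = colnames(cts))
#' me <- MicrobiomeExperiment(cts, metadata = md)
#' pickSamples(me, "b", mode = "discard")
pickSamples <- function(exp, ids, mode = c("keep", "discard")) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  kept <- pick_ids(sampleIds(exp), ids, match.arg(mode), "sample")
  out <- exp[, kept]
  validObject(out)
  out
}

#' @rdname pickSamples
#' @export
pickFeatures <- function(exp, ids, mode = c("keep", "discard")) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  kept <- pick_ids(featureIds(exp), ids, match.arg(mode), "feature")
  out <- exp[kept, ]
  validObject(out)
  out
}

# Assays ------------------------------------------------------------------

#' Retrieve a derived abundance assay
#'
#' `"counts"` returns the stored matrix verbatim; `"relabu"` column-
#' normalises to relative abundances; `"logcpm"` applies
#' log2(counts-per-million + 1). See [countsToRelabu()] and
#' [countsToLogCPM()] for the formulas.
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @param kind One of `"counts"`, `"relabu"`, `"logcpm"`.
#' @return Numeric matrix with the same dimnames as the counts.
#' @export
getAssay <- function(exp, kind = c("counts", "relabu", "logcpm")) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  kind <- match.arg(kind)
  cts <- meCounts(exp)
  switch(kind,
         counts = cts,
         relabu = countsToRelabu(cts),
         logcpm = countsToLogCPM(cts))
}

# Summary -----------------------------------------------------------------

# A metadata column is continuous iff numeric with more than `threshold`
# distinct non-missing values; otherwise categorical.
covariate_type <- function(v, threshold = 8L) {
  if (is.numeric(v) && length(unique(v[!is.na(v)])) > threshold) {
    "continuous"
  } else {
    "categorical"
  }
}

#' Summary statistics for a MicrobiomeExperiment
#'
#' Per-sample library sizes, per-feature mean counts / prevalence / mean
#' relative abundance, and a covariate type census (a covariate is called
#' continuous when numeric with more than 8 distinct values).
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @return A list with data frames `samples` (sample_id, library_size),
#'   `features` (feature_id, mean_count, prevalence, mean_relabu) and
#'   `covariates` (name, type).
#' @export
experimentSummary <- function(exp) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  cts <- meCounts(exp)
  lib <- colSums(cts)
  rel <- sweep(cts, 2L, ifelse(lib > 0, lib, 1), "/")
  md <- sampleData(exp)
  types <- vapply(md, covariate_type, character(1))
  list(
    samples = data.frame(sample_id = sampleIds(exp), library_size = lib,
                         row.names = NULL),
    features = data.frame(
      feature_id = featureIds(exp),
      mean_count = rowMeans(cts),
      prevalence = rowMeans(cts > 0),
      mean_relabu = rowMeans(rel),
      row.names = NULL
    ),
    covariates = data.frame(name = colnames(md),
                            type = unname(types), row.names = NULL)
  )
}
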