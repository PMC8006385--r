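# Abundance transforms, taxonomy aggregation, filtering, discretization.

#' Convert counts to relative abundances
#'
#' Each sample (column) is divided by its library size, so columns are
#' points on the simplex.
#'
#' @param counts Numeric matrix, features x samples, no all-zero column.
#' @return Matrix of per-sample proportions, same dimnames.
#' @export
#' @examples
#' countsToRelabu(matrix(c(2, 3, 5), 3, dimnames = list(letters[1:3], "S1")))
countsToRelabu <- function(counts) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    bad <- colnames(counts)[which(lib <= 0)]
    if (is.null(bad)) bad <- which(lib <= 0)
    stop_validation(sprintf("all-zero sample column(s): %s",
                            paste(bad, collapse = ", ")))
  }
  sweep(counts, 2L, lib, "/")
}

#' Convert counts to log2 counts-per-million
#'
#' Computes `log2(c * 1e6 / L + 1)` with `L` the library size of the
#' sample, so zero counts map exactly to 0 and the transform is invariant
#' to scaling all counts in a sample.
#'
#' @inheritParams countsToRelabu
#' @return Matrix of logCPM values, same dimnames.
#' @export
countsToLogCPM <- function(counts) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    bad <- colnames(counts)[which(lib <= 0)]
    if (is.null(bad)) bad <- which(lib <= 0)
    stop_validation(sprintf("all-zero sample column(s): %s",
                            paste(bad, collapse = ", ")))
  }
  log2(sweep(counts, 2L, lib, "/") * 1e6 + 1)
}

#' Aggregate counts to a higher taxonomy level
#'
#' Features sharing the same label at `level` are summed per sample; the
#' aggregated features take the level labels as ids (order of first
#' appearance). Taxonomy is truncated to ranks at or above `level`; within
#' an aggregated group a coarser rank is kept only when unanimous,
#' otherwise it becomes [unclassifiedMarker()]. Column sums are conserved
#' exactly.
#'
#' @param exp A [MicrobiomeExperiment-class] with taxonomy.
#' @param level A rank from [taxonomyRanks()], present in the taxonomy.
#' @return A [MicrobiomeExperiment-class] at the requested level.
#' @export
upsampleCounts <- function(exp, level) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  tax <- taxonomyTable(exp)
  if (is.null(tax)) stop_validation("taxonomy is absent; cannot aggregate")
  level <- tolower(level)
  if (!level %in% taxonomyRanks()) {
    stop_validation(sprintf("unknown rank '%s'", level))
  }
  if (!level %in% colnames(tax)) {
    stop_validation(sprintf("rank '%s' not present in taxonomy", level))
  }
  labels <- tax[[level]]
  groups <- factor(labels, levels = unique(labels))
  cts <- meCounts(exp)
  agg <- rowsum(cts, groups, reorder = FALSE)
  storage.mode(agg) <- "double"

  keep_ranks <- taxonomyRanks()[seq_len(match(level, taxonomyRanks()))]
  keep_ranks <- keep_ranks[keep_ranks %in% colnames(tax)]
  new_tax <- do.call(rbind, lapply(levels(groups), function(g) {
    sub <- tax[labels == g, keep_ranks, drop = FALSE]
    vapply(sub, function(col) {
      u <- unique(col)
      if (length(u) == 1L) u else unclassifiedMarker()
    }, character(1))
  }))
  new_tax <- as.data.frame(new_tax, stringsAsFactors = FALSE)
  rownames(new_tax) <- levels(groups)
  new_tax[[level]] <- levels(groups)

  MicrobiomeExperiment(agg, taxonomy = new_tax, metadata = sampleData(exp))
}

#' Filter features by abundance criteria
#'
#' Keeps features satisfying **all** thresholds: mean raw count >=
#' `min_avg_reads`, mean relative abundance >= `min_mean_relabu`, and
#' prevalence (fraction of samples with a nonzero count) >=
#' `min_prevalence`; features in `explicit_discard` are removed regardless.
#' A per-feature report of removals (first criterion failed) is attached
#' as `metadata(result)$filterReport` and returned invisibly-accessible
#' via [filterReport()].
#'
#' The operation is idempotent for threshold-only specs: re-applying the
#' same spec to its own output removes nothing further, because the
#' criteria are recomputed on the already-conforming set.
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @param min_avg_reads Minimum mean raw count (>= 0).
#' @param min_mean_relabu Minimum mean relative abundance in \[0, 1\].
#' @param min_prevalence Minimum prevalence in \[0, 1\].
#' @param explicit_discard Character vector of feature ids to drop.
#' @return Filtered [MicrobiomeExperiment-class] with a `filterReport`
#'   in its metadata.
#' @export
filterFeatures <- function(exp, min_avg_reads = 0, min_mean_relabu = 0,
                           min_prevalence = 0, explicit_discard = character()) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  if (!is_number(min_avg_reads) || min_avg_reads < 0) {
    stop_validation("min_avg_reads must be a non-negative number")
  }
  if (!is_number(min_mean_relabu) || min_mean_relabu < 0 ||
      min_mean_relabu > 1) {
    stop_validation("min_mean_relabu must lie in [0, 1]")
  }
  if (!is_number(min_prevalence) || min_prevalence < 0 ||
      min_prevalence > 1) {
    stop_validation("min_prevalence must lie in [0, 1]")
  }
  unknown <- setdiff(explicit_discard, featureIds(exp))
  if (length(unknown)) {
    stop_validation(sprintf("unknown feature id(s) in explicit_discard: %s",
                            paste(unknown, collapse = ", ")))
  }
  s <- experimentSummary(exp)$features
  fail_crit <- rep(NA_character_, nrow(s))
  fail_val <- rep(NA_real_, nrow(s))
  set <- function(idx, crit, val) {
    fresh <- idx & is.na(fail_crit)
    fail_crit[fresh] <<- crit
    fail_val[fresh] <<- val[fresh]
  }
  set(s$feature_id %in% explicit_discard, "explicit_discard", s$mean_count)
  set(s$mean_count < min_avg_reads, "min_avg_reads", s$mean_count)
  set(s$mean_relabu < min_mean_relabu, "min_mean_relabu", s$mean_relabu)
  set(s$prevalence < min_prevalence, "min_prevalence", s$prevalence)
  removed <- !is.na(fail_crit)
  if (all(removed)) {
    stop_validation("filter spec would remove all features")
  }
  report <- data.frame(feature_id = s$feature_id[removed],
                       criterion = fail_crit[removed],
                       value = fail_val[removed], row.names = NULL)
  out <- if (any(removed)) {
    pickFeatures(exp, s$feature_id[removed], mode = "discard")
  } else {
    exp
  }
  S4Vectors::metadata(out)$filterReport <- report
  out
}

#' Retrieve the removal report attached by [filterFeatures()]
#' @param exp A filtered [MicrobiomeExperiment-class].
#' @return Data frame (feature_id, criterion, value), or `NULL`.
#' @export
filterReport <- function(exp) S4Vectors::metadata(exp)$filterReport

#' Filter samples by covariate predicate or explicit ids
#'
#' Exactly one selector is used: `values` (membership / equality on a
#' categorical or discrete covariate), `range` (inclusive numeric interval
#' `c(lo, hi)` on a continuous covariate), or `ids` (explicit keep list).
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @param covariate Covariate name (required for `values`/`range`).
#' @param values Values to keep (membership test).
#' @param range Length-2 numeric `c(lo, hi)`, inclusive; `-Inf`/`Inf` allowed.
#' @param ids Explicit sample ids to keep.
#' @return Coordinated sample subset of `exp`.
#' @export
filterSamples <- function(exp, covariate = NULL, values = NULL, range = NULL,
                          ids = NULL) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  n_sel <- sum(!is.null(values), !is.null(range), !is.null(ids))
  if (n_sel != 1L) {
    stop_validation("provide exactly one of values=, range=, ids=")
  }
  if (!is.null(ids)) return(pickSamples(exp, ids, mode = "keep"))
  md <- sampleData(exp)
  if (is.null(covariate) || !covariate %in% colnames(md)) {
    stop_validation(sprintf("unknown covariate '%s'",
                            if (is.null(covariate)) "" else covariate))
  }
  v <- md[[covariate]]
  keep <- if (!is.null(values)) {
    as.character(v) %in% as.character(values)
  } else {
    if (!is.numeric(v)) {
      stop_validation(sprintf("covariate '%s' is not numeric; range predicate
 requires a continuous covariate", covariate))
    }
    if (length(range) != 2L) stop_validation("range must be c(lo, hi)")
    !is.na(v) & v >= range[1L] & v <= range[2L]
  }
  if (!any(keep)) stop_validation("predicate matches no samples")
  pickSamples(exp, sampleIds(exp)[keep], mode = "keep")
}

#' Discretize a continuous covariate into bins
#'
#' Default binning is quantile-based (equal counts up to ties); equal-width
#' bins or explicit breakpoints are available. Bins are left-closed,
#' right-open `[lo, hi)` except the final bin which is closed `[lo, hi]`.
#'
#' @param values Numeric vector.
#' @param n_bins Integer >= 2; number of bins (ignored when `breaks` given).
#' @param breaks Optional explicit breakpoints (strictly increasing,
#'   spanning the data); honoured verbatim.
#' @param equal_width Use equal-width instead of quantile bins.
#' @return List with `factor` (binned values) and `labels` (bin labels).
#' @export
#' @examples
#' categorizeCovariate(1:10, n_bins = 2)$labels
categorizeCovariate <- function(values, n_bins = NULL, breaks = NULL,
                                equal_width = FALSE) {
  if (!is.numeric(values)) stop_validation("values must be numeric")
  if (is.null(breaks)) {
    if (is.null(n_bins) || !is_number(n_bins) || n_bins < 2) {
      stop_validation("n_bins must be an integer >= 2")
    }
    n_distinct <- length(unique(values[!is.na(values)]))
    if (n_distinct < 2L) stop_validation("cannot bin a constant vector")
    if (n_bins > n_distinct) {
      stop_validation("n_bins exceeds the number of distinct values")
    }
    breaks <- if (equal_width) {
      seq(min(values, na.rm = TRUE), max(values, na.rm = TRUE),
          length.out = n_bins + 1L)
    } else {
      unname(stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1L),
                             na.rm = TRUE))
    }
    breaks <- unique(breaks)
  }
  if (length(breaks) < 2L || is.unsorted(breaks, strictly = TRUE)) {
    stop_validation("degenerate breakpoints: need >= 2 strictly increasing values")
  }
  labels <- paste0("[", format(breaks[-length(breaks)], trim = TRUE), ",",
                   format(breaks[-1L], trim = TRUE),
                   c(rep(")", length(breaks) - 2L), "]"))
  f <- cut(values, breaks = breaks, labels = labels, right = FALSE,
           include.lowest = TRUE)
  list(factor = f, labels = labels)
}
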