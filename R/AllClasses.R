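#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

# MicrobiomeExperiment ----------------------------------------------------

#' MicrobiomeExperiment: coordinated microbiome count container
#'
#' An S4 class holding a raw read-count matrix (features x samples), an
#' optional per-feature taxonomy table and a per-sample metadata table,
#' kept in guaranteed alignment. It extends
#' [SummarizedExperiment::SummarizedExperiment]: the count matrix is the
#' `"counts"` assay, taxonomy lives in `rowData()` and sample metadata in
#' `colData()`, so the full Bioconductor subsetting and accessor machinery
#' applies.
#'
#' Validity requires: non-negative integral counts; unique, non-empty
#' feature and sample identifiers; taxonomy columns drawn from
#' [taxonomyRanks()] in canonical order with no empty strings (missing
#' assignments carry the [unclassifiedMarker()]).
#'
#' @seealso [MicrobiomeExperiment()] for construction,
#'   [pickSamples()]/[pickFeatures()] for coordinated subsetting.
#' @export
setClass("MicrobiomeExperiment", contains = "SummarizedExperiment")

validate_me <- function(object) {
  msgs <- character()
  if (!("counts" %in% SummarizedExperiment::assayNames(object))) {
    return("assay 'counts' is missing")
  }
  cts <- SummarizedExperiment::assay(object, "counts")
  fid <- rownames(object)
  sid <- colnames(object)
  if (is.null(fid) || any(is.na(fid)) || any(fid == "")) {
    msgs <- c(msgs, "feature ids must be non-empty strings")
  } else if (anyDuplicated(fid)) {
    msgs <- c(msgs, sprintf("duplicate feature ids: %s",
                            paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  }
  if (is.null(sid) || any(is.na(sid)) || any(sid == "")) {
    msgs <- c(msgs, "sample ids must be non-empty strings")
  } else if (anyDuplicated(sid)) {
    msgs <- c(msgs, sprintf("duplicate sample ids: %s",
                            paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  if (!is.numeric(cts)) {
    msgs <- c(msgs, "counts must be numeric")
  } else {
    if (any(cts < 0)) {
      bad <- which(cts < 0, arr.ind = TRUE)[1L, ]
      msgs <- c(msgs, sprintf("negative count for feature '%s', sample '%s'",
                              fid[bad[1L]], sid[bad[2L]]))
    }
    if (any(abs(cts - round(cts)) > 1e-9)) {
      bad <- which(abs(cts - round(cts)) > 1e-9, arr.ind = TRUE)[1L, ]
      msgs <- c(msgs, sprintf("non-integer count for feature '%s', sample '%s'",
                              fid[bad[1L]], sid[bad[2L]]))
    }
  }
  tax <- SummarizedExperiment::rowData(object)
  if (ncol(tax) > 0L) {
    ranks <- colnames(tax)
    known <- taxonomyRanks()
    if (!all(ranks %in% known)) {
      msgs <- c(msgs, sprintf("unknown taxonomy ranks: %s",
                              paste(setdiff(ranks, known), collapse = ", ")))
    } else if (!identical(ranks, known[known %in% ranks])) {
      msgs <- c(msgs, "taxonomy ranks are not in canonical order")
    }
    for (r in ranks) {
      v <- tax[[r]]
      if (!is.character(v) || any(is.na(v)) || any(v == "")) {
        msgs <- c(msgs, sprintf(
          "taxonomy rank '%s' must be character with explicit '%s' for missing",
          r, unclassifiedMarker()))
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("MicrobiomeExperiment", validate_me)

# DistanceMatrix ----------------------------------------------------------

#' DistanceMatrix: pairwise sample dissimilarities
#'
#' Symmetric matrix of pairwise sample dissimilarities with a zero diagonal
#' and a metric label. Both supported metrics (Bray-Curtis and binary
#' Jaccard) are bounded in \[0, 1\].
#'
#' @slot dist Symmetric numeric matrix with sample ids as dimnames.
#' @slot metric Metric label, `"bray_curtis"` or `"jaccard"`.
#' @seealso [betaDistance()]
#' @export
setClass("DistanceMatrix",
         representation(dist = "matrix", metric = "character"))

setValidity("DistanceMatrix", function(object) {
  d <- object@dist
  msgs <- character()
  if (nrow(d) != ncol(d)) msgs <- c(msgs, "matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d))) {
    msgs <- c(msgs, "dimnames must be identical sample ids")
  }
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
    msgs <- c(msgs, "matrix must be symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) msgs <- c(msgs, "diagonal must be zero")
  if (any(d < -1e-12) || any(d > 1 + 1e-12)) {
    msgs <- c(msgs, "entries must lie in [0, 1]")
  }
  if (!is_string(object@metric)) msgs <- c(msgs, "metric must be a string")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn DistanceMatrix-class number of samples
#' @param x,object A `DistanceMatrix`.
#' @export
setMethod("dim", "DistanceMatrix", function(x) dim(x@dist))

#' Extract the dissimilarity matrix or metric label
#'
#' @param x A [DistanceMatrix-class] object.
#' @return `distMatrix()` the plain symmetric matrix; `distMetric()` the
#'   metric label string.
#' @export
distMatrix <- function(x) {
  stopifnot(is(x, "DistanceMatrix"))
  x@dist
}

#' @rdname distMatrix
#' @export
distMetric <- function(x) {
  stopifnot(is(x, "DistanceMatrix"))
  x@metric
}

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix: %d samples, metric = %s\n",
              nrow(object@dist), object@metric))
})

# Embedding ---------------------------------------------------------------

#' Embedding: low-dimensional sample coordinates
#'
#' Result of a dimension-reduction method. For PCA/PCoA the per-axis
#' explained-variance fractions are populated (non-increasing, in \[0,1\]);
#' for t-SNE/UMAP they are empty.
#'
#' @slot coordinates n_samples x k numeric matrix, axis labels as colnames.
#' @slot explained_variance Numeric vector (possibly empty) of per-axis
#'   explained-variance fractions.
#' @slot method Method label ("pca", "pcoa", "tsne", "umap").
#' @slot details List of method diagnostics (e.g. dropped negative
#'   eigenvalues for PCoA).
#' @export
setClass("Embedding",
         representation(coordinates = "matrix",
                        explained_variance = "numeric",
                        method = "character",
                        details = "list"))

setValidity("Embedding", function(object) {
  ev <- object@explained_variance
  msgs <- character()
  if (length(ev)) {
    if (any(ev < -1e-12) || any(ev > 1 + 1e-12)) {
      msgs <- c(msgs, "explained variance fractions must lie in [0,1]")
    }
    if (is.unsorted(rev(ev), strictly = FALSE)) {
      msgs <- c(msgs, "explained variance must be non-increasing")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Accessors for Embedding objects
#' @param x An [Embedding-class] object.
#' @return `embCoordinates()`: sample x axis coordinate matrix;
#'   `embExplainedVariance()`: per-axis explained-variance fractions;
#'   `embMethod()`: method label.
#' @export
embCoordinates <- function(x) {
  stopifnot(is(x, "Embedding"))
  x@coordinates
}

#' @rdname embCoordinates
#' @export
embExplainedVariance <- function(x) {
  stopifnot(is(x, "Embedding"))
  x@explained_variance
}

#' @rdname embCoordinates
#' @export
embMethod <- function(x) {
  stopifnot(is(x, "Embedding"))
  x@method
}

setMethod("show", "Embedding", function(object) {
  cat(sprintf("Embedding: %s, %d samples x %d axes\n", object@method,
              nrow(object@coordinates), ncol(object@coordinates)))
  if (length(object@explained_variance)) {
    cat("  explained variance:",
        paste(sprintf("%.1f%%", 100 * object@explained_variance),
              collapse = ", "), "\n")
  }
})

# BiomarkerResult ---------------------------------------------------------

#' BiomarkerResult: cross-validated biomarker selection output
#'
#' @slot selected Character vector of selected feature ids (importance score
#'   at or above the cutoff).
#' @slot importance Named numeric vector: per-feature importance score, the
#'   fraction of cross-validation folds whose candidate set contained the
#'   feature (multiples of 1/(N*K) when no fold is skipped).
#' @slot fold_auc Numeric vector of per-evaluation-fold ROC AUCs.
#' @slot mean_auc Mean of the per-fold AUCs.
#' @slot roc Data frame with columns `fpr` and `mean_tpr`: the vertically
#'   averaged ROC curve on a fixed 101-point false-positive-rate grid.
#' @slot config List echoing the configuration used.
#' @seealso [findBiomarker()]
#' @export
setClass("BiomarkerResult",
         representation(selected = "character",
                        importance = "numeric",
                        fold_auc = "numeric",
                        mean_auc = "numeric",
                        roc = "data.frame",
                        config = "list"))

setMethod("show", "BiomarkerResult", function(object) {
  cat(sprintf("BiomarkerResult: %d selected feature(s), mean CV AUC = %.3f\n",
              length(object@selected), object@mean_auc))
  if (length(object@selected)) {
    top <- sort(object@importance[object@selected], decreasing = TRUE)
    cat("  ", paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "),
        "\n", sep = "")
  }
})

#' Accessors for BiomarkerResult objects
#' @param x A [BiomarkerResult-class] object.
#' @return `selectedFeatures()`: ids of features passing the importance
#'   cutoff; `importanceScores()`: named per-feature score vector;
#'   `foldAUC()`: per-fold AUCs; `meanAUC()`: their mean; `rocCurve()`:
#'   averaged ROC curve data frame.
#' @export
selectedFeatures <- function(x) {
  stopifnot(is(x, "BiomarkerResult"))
  x@selected
}

#' @rdname selectedFeatures
#' @export
importanceScores <- function(x) {
  stopifnot(is(x, "BiomarkerResult"))
  x@importance
}

#' @rdname selectedFeatures
#' @export
foldAUC <- function(x) {
  stopifnot(is(x, "BiomarkerResult"))
  x@fold_auc
}

#' @rdname selectedFeatures
#' @export
meanAUC <- function(x) {
  stopifnot(is(x, "BiomarkerResult"))
  x@mean_auc
}

#' @rdname selectedFeatures
#' @export
rocCurve <- function(x) {
  stopifnot(is(x, "BiomarkerResult"))
  x@roc
}
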