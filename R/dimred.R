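# PCA and PCoA (classical MDS), plus delegated t-SNE/UMAP backends.

# Orient each axis so that its largest-magnitude loading (or coordinate,
# when no loadings exist) is positive — makes outputs reproducible across
# numerically equivalent backends.
orient_axes <- function(scores, loadings = NULL) {
  ref <- if (is.null(loadings)) scores else loadings
  for (j in seq_len(ncol(scores))) {
    v <- ref[, j]
    if (v[which.max(abs(v))] < 0) {
      scores[, j] <- -scores[, j]
      if (!is.null(loadings)) loadings[, j] <- -loadings[, j]
    }
  }
  scores
}

#' Principal components analysis of sample abundance profiles
#'
#' Features are aggregated to `level` (when given), the chosen assay
#' transform applied, and the samples-by-features matrix mean-centered
#' feature-wise (no scaling by default: abundance variances are
#' meaningful). Scores are projections onto the top right-singular
#' directions; per-axis explained variance is the eigenvalue fraction of
#' the total.
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @param k Number of axes (2 or 3).
#' @param assay Assay fed to the decomposition (`"logcpm"` default).
#' @param level Optional taxonomy rank to aggregate to first.
#' @param scale. Scale features to unit variance before the SVD.
#' @return An [Embedding-class] with method `"pca"`.
#' @export
runPCA <- function(exp, k = 2, assay = c("logcpm", "counts", "relabu"),
                   level = NULL, scale. = FALSE) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  assay <- match.arg(assay)
  if (!k %in% c(2L, 3L)) stop_validation("k must be 2 or 3")
  if (!is.null(level)) exp <- upsampleCounts(exp, level)
  x <- t(getAssay(exp, assay))  # samples x features
  n <- nrow(x)
  if (n < 2L) stop_validation("need at least 2 samples")
  # at most n-1 nontrivial axes exist after centering; truncate the request
  k <- min(k, n - 1L, ncol(x))
  if (all(abs(sweep(x, 2L, colMeans(x))) < 1e-12)) {
    stop_validation("constant matrix: no variance to decompose")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2
  ev_frac <- ev / sum(ev)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  scores <- orient_axes(scores, pc$rotation[, seq_len(k), drop = FALSE])
  colnames(scores) <- paste0("PC", seq_len(k))
  new("Embedding", coordinates = scores,
      explained_variance = ev_frac[seq_len(k)],
      method = "pca", details = list(assay = assay, scaled = scale.))
}

#' Principal coordinates analysis (classical MDS) of a distance matrix
#'
#' Applies Gower double-centering `B = -1/2 * J D^2 J` with
#' `J = I - 11'/n`, eigendecomposes B, and returns coordinates
#' `v_i * sqrt(lambda_i)` for the top positive eigenvalues. Negative
#' eigenvalues (non-Euclidean distances) are dropped; their count and
#' total magnitude are reported in the embedding details. Explained
#' variance is relative to the sum of positive eigenvalues.
#'
#' @param D A [DistanceMatrix-class] (or plain symmetric matrix).
#' @param k Number of axes (2 or 3).
#' @return An [Embedding-class] with method `"pcoa"`.
#' @export
runPCoA <- function(D, k = 2) {
  d <- if (is(D, "DistanceMatrix")) D@dist else D
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (!k %in% c(2L, 3L)) stop_validation("k must be 2 or 3")
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  pos <- eig$values > 1e-12 * max(abs(eig$values), 1e-300)
  n_pos <- sum(pos)
  if (k > n_pos) {
    stop_validation(sprintf(
      "k = %d exceeds the number of positive eigenvalues (%d)", k, n_pos))
  }
  lambda <- eig$values[pos]
  vec <- eig$vectors[, pos, drop = FALSE]
  coords <- sweep(vec[, seq_len(k), drop = FALSE], 2L,
                  sqrt(lambda[seq_len(k)]), "*")
  coords <- orient_axes(coords)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(k))
  neg <- eig$values[eig$values < 0]
  new("Embedding", coordinates = coords,
      explained_variance = (lambda / sum(lambda))[seq_len(k)],
      method = "pcoa",
      details = list(n_negative_eigenvalues = length(neg),
                     negative_eigenvalue_magnitude = sum(abs(neg))))
}

# Delegated nonlinear embeddings -----------------------------------------

prepare_embedding_input <- function(exp, assay, level) {
  if (!is.null(level)) exp <- upsampleCounts(exp, level)
  t(getAssay(exp, assay))
}

#' Nonlinear embeddings delegated to optional backends
#'
#' t-SNE (package Rtsne) and UMAP (package uwot) run behind a delegation
#' contract: identical seed and input give identical output of shape
#' `n x k`, with no explained-variance fields. When the backend package is
#' not installed a typed capability error (class `mbkit_capability_error`)
#' is raised; the rest of the toolkit functions without it.
#'
#' @inheritParams runPCA
#' @param perplexity t-SNE perplexity.
#' @param n_neighbors UMAP neighborhood size.
#' @param seed Integer RNG seed (mandatory).
#' @return An [Embedding-class] with method `"tsne"` or `"umap"`.
#' @export
runTSNE <- function(exp, k = 2, assay = c("logcpm", "counts", "relabu"),
                    level = NULL, perplexity = 10, seed) {
  assay <- match.arg(assay)
  if (missing(seed)) stop_validation("runTSNE requires a seed")
  if (!requireNamespace("Rtsne", quietly = TRUE)) {
    stop_capability("t-SNE backend unavailable: install the 'Rtsne' package")
  }
  x <- prepare_embedding_input(exp, assay, level)
  if (nrow(x) < 4L) stop_validation("need at least 4 samples")
  set.seed(as.integer(seed))
  fit <- Rtsne::Rtsne(x, dims = k, perplexity = perplexity,
                      check_duplicates = FALSE, pca = TRUE)
  coords <- fit$Y
  dimnames(coords) <- list(rownames(x), paste0("tSNE", seq_len(k)))
  new("Embedding", coordinates = coords, explained_variance = numeric(),
      method = "tsne", details = list(perplexity = perplexity, seed = seed))
}

#' @rdname runTSNE
#' @export
runUMAP <- function(exp, k = 2, assay = c("logcpm", "counts", "relabu"),
                    level = NULL, n_neighbors = 15, seed) {
  assay <- match.arg(assay)
  if (missing(seed)) stop_validation("runUMAP requires a seed")
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop_capability("UMAP backend unavailable: install the 'uwot' package")
  }
  x <- prepare_embedding_input(exp, assay, level)
  if (nrow(x) < 4L) stop_validation("need at least 4 samples")
  set.seed(as.integer(seed))
  coords <- uwot::umap(x, n_components = k,
                       n_neighbors = min(n_neighbors, nrow(x) - 1L))
  dimnames(coords) <- list(rownames(x), paste0("UMAP", seq_len(k)))
  new("Embedding", coordinates = coords, explained_variance = numeric(),
      method = "umap", details = list(n_neighbors = n_neighbors, seed = seed))
}

#' Write an embedding as a plot-ready TSV
#'
#' One row per sample: id, axis coordinates, plus any sample covariates
#' supplied, so the file can be fed straight to a plotting tool.
#'
#' @param embedding An [Embedding-class].
#' @param path Output TSV path.
#' @param metadata Optional data frame of covariates (rownames = ids).
#' @return `path`, invisibly.
#' @export
writeEmbedding <- function(embedding, path, metadata = NULL) {
  stopifnot(is(embedding, "Embedding"))
  co <- embedding@coordinates
  out <- data.frame(sample_id = rownames(co), co, check.names = FALSE,
                    row.names = NULL)
  if (!is.null(metadata)) {
    out <- cbind(out, metadata[rownames(co), , drop = FALSE])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
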