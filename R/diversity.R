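# Alpha diversity metrics and tests; beta diversity distances and tests.

#' Per-sample alpha diversity
#'
#' Computes, on per-sample proportions p_i (after optional aggregation to a
#' taxonomy level):
#' Shannon `-sum(p_i * log(p_i))` (zero-proportion terms contribute 0,
#' natural log), Gini-Simpson `1 - sum(p_i^2)`, inverse Simpson
#' `1 / sum(p_i^2)`, and richness, the number of taxa with a nonzero count.
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @param metric One of `"shannon"`, `"gini_simpson"`, `"inverse_simpson"`,
#'   `"richness"`.
#' @param level Optional taxonomy rank at which to aggregate first.
#' @return Named numeric vector, one value per sample.
#' @export
#' @examples
#' cts <- matrix(c(1, 1, 1, 1), 4, 1,
#'               dimnames = list(paste0("t", 1:4), "S1"))
#' me <- MicrobiomeExperiment(cts, metadata = data.frame(row.names = "S1"))
#' alphaDiversity(me, "shannon")  # log(4)
alphaDiversity <- function(exp,
                           metric = c("shannon", "gini_simpson",
                                      "inverse_simpson", "richness"),
                           level = NULL) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  metric <- match.arg(metric)
  if (!is.null(level)) exp <- upsampleCounts(exp, level)
  cts <- meCounts(exp)
  if (any(colSums(cts) <= 0)) {
    stop_validation("alpha diversity undefined for all-zero sample(s)")
  }
  p <- countsToRelabu(cts)
  out <- switch(metric,
    shannon = apply(p, 2L, function(q) {
      q <- q[q > 0]
      -sum(q * log(q))
    }),
    gini_simpson = 1 - colSums(p^2),
    inverse_simpson = 1 / colSums(p^2),
    richness = colSums(cts > 0)
  )
  stats::setNames(as.numeric(out), colnames(cts))
}

#' Group test for per-sample alpha diversity values
#'
#' Two-group methods: Wilcoxon rank-sum (exact enumeration when both
#' groups have at most 8 samples and there are no ties, otherwise the
#' tie-corrected normal approximation with continuity correction) and
#' Welch's unequal-variance two-sided t test. `kruskal_wallis` (tie-
#' corrected H against chi-square with groups-1 df) accepts two or more
#' groups.
#'
#' @param values Numeric per-sample vector (e.g. from [alphaDiversity()]).
#' @param groups Categorical vector of the same length.
#' @param method `"wilcoxon"`, `"t_test"`, or `"kruskal_wallis"`.
#' @return An object of class `htest` (statistic, p.value, method).
#' @export
alphaDivTest <- function(values, groups,
                         method = c("wilcoxon", "t_test", "kruskal_wallis")) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (length(values) != length(groups)) {
    stop_validation("values and groups must have equal length")
  }
  ng <- nlevels(groups)
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop_validation("each group needs at least 2 samples")
  }
  if (method %in% c("wilcoxon", "t_test") && ng != 2L) {
    stop_validation(sprintf("%s requires exactly 2 groups (got %d)",
                            method, ng))
  }
  if (ng < 2L) stop_validation("need at least 2 groups")
  switch(method,
    wilcoxon = {
      x <- values[groups == levels(groups)[1L]]
      y <- values[groups == levels(groups)[2L]]
      no_ties <- !any(duplicated(c(x, y)))
      use_exact <- length(x) <= 8L && length(y) <= 8L && no_ties
      stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
    },
    t_test = {
      x <- values[groups == levels(groups)[1L]]
      y <- values[groups == levels(groups)[2L]]
      stats::t.test(x, y, var.equal = FALSE)
    },
    kruskal_wallis = stats::kruskal.test(values, groups)
  )
}

# Beta diversity ----------------------------------------------------------

bray_curtis_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)
jaccard_pair <- function(x, y) {
  a <- x > 0
  b <- y > 0
  1 - sum(a & b) / sum(a | b)
}

#' Pairwise beta-diversity distances between samples
#'
#' Bray-Curtis: `sum(|x - y|) / sum(x + y)` over feature abundances;
#' Jaccard: `1 - |A intersect B| / |A union B|` on presence/absence of the
#' raw counts (binary form). By default Bray-Curtis is computed on relative
#' abundances, removing the library-size confound; set `assay = "counts"`
#' for raw-count distances. Jaccard always uses raw-count presence.
#'
#' @param exp A [MicrobiomeExperiment-class] (or a plain numeric matrix of
#'   features x samples).
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @param assay Assay fed to Bray-Curtis: `"relabu"` (default), `"counts"`
#'   or `"logcpm"`.
#' @param level Optional taxonomy rank at which to aggregate first.
#' @return A [DistanceMatrix-class].
#' @export
#' @examples
#' m <- cbind(S1 = c(6, 4, 0), S2 = c(2, 4, 8))
#' rownames(m) <- paste0("t", 1:3)
#' distMatrix(betaDistance(m, "bray_curtis", assay = "counts"))[1, 2]  # 0.5
betaDistance <- function(exp, metric = c("bray_curtis", "jaccard"),
                         assay = c("relabu", "counts", "logcpm"),
                         level = NULL) {
  metric <- match.arg(metric)
  assay <- match.arg(assay)
  if (is(exp, "MicrobiomeExperiment")) {
    if (!is.null(level)) exp <- upsampleCounts(exp, level)
    cts <- meCounts(exp)
  } else {
    stopifnot(is.matrix(exp), is.numeric(exp))
    cts <- exp
    if (is.null(colnames(cts))) {
      colnames(cts) <- paste0("S", seq_len(ncol(cts)))
    }
  }
  n <- ncol(cts)
  if (n < 2L) stop_validation("need at least 2 samples")
  if (any(colSums(cts) <= 0)) {
    stop_validation("beta distance undefined with all-zero sample(s)")
  }
  x <- if (metric == "bray_curtis") {
    switch(assay, relabu = countsToRelabu(cts),
           counts = cts, logcpm = countsToLogCPM(cts))
  } else {
    cts
  }
  pairfun <- if (metric == "bray_curtis") bray_curtis_pair else jaccard_pair
  d <- matrix(0, n, n, dimnames = list(colnames(cts), colnames(cts)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- pairfun(x[, i], x[, j])
    }
  }
  new("DistanceMatrix", dist = d, metric = metric)
}

#' Decompose pairwise distances by two-group membership
#'
#' Partitions the strict upper-triangle sample pairs into within-group-1,
#' within-group-2 and between-group distances.
#'
#' @param D A [DistanceMatrix-class].
#' @param groups Two-level categorical vector aligned with the samples.
#' @return List of numeric vectors `within_g1`, `within_g2`, `between`,
#'   with the group labels stored in `names(<list>$labels)`.
#' @export
betaGroupDistances <- function(D, groups) {
  stopifnot(is(D, "DistanceMatrix"))
  groups <- factor(groups)
  if (nlevels(groups) != 2L) {
    stop_validation("groups must have exactly 2 levels")
  }
  if (length(groups) != nrow(D@dist)) {
    stop_validation("groups length must match the number of samples")
  }
  if (any(table(groups) < 2L)) {
    stop_validation("each group needs at least 2 samples")
  }
  d <- D@dist
  n <- nrow(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  gi <- groups[idx[, 1L]]
  gj <- groups[idx[, 2L]]
  vals <- d[idx]
  l1 <- levels(groups)[1L]
  l2 <- levels(groups)[2L]
  list(
    within_g1 = vals[gi == l1 & gj == l1],
    within_g2 = vals[gi == l2 & gj == l2],
    between = vals[gi != gj],
    labels = c(g1 = l1, g2 = l2)
  )
}

#' Write / read a distance matrix as square TSV
#'
#' The file is a square matrix with sample ids as header and first column;
#' the metric label is recorded on a `# metric:` comment line.
#'
#' @param D A [DistanceMatrix-class].
#' @param path File path.
#' @return `writeDistanceMatrix()`: `path` invisibly;
#'   `readDistanceMatrix()`: a [DistanceMatrix-class].
#' @export
writeDistanceMatrix <- function(D, path) {
  stopifnot(is(D, "DistanceMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metric: %s", D@metric), con)
  d <- D@dist
  writeLines(paste(c("sample_id", colnames(d)), collapse = "\t"), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(rownames(d)[i], sprintf("%.17g", d[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  metric <- sub("^# metric:\\s*", "", lines[1L])
  tab <- utils::read.delim(text = lines[-1L], row.names = 1L,
                           check.names = FALSE)
  d <- as.matrix(tab)
  new("DistanceMatrix", dist = d, metric = metric)
}

#' Distance-based group test for beta diversity
#'
#' `"permanova"` delegates to [permanova()]. `"wilcoxon"` and
#' `"kruskal_wallis"` compare the pooled within-group distances against
#' the between-group distances from [betaGroupDistances()].
#'
#' @param D A [DistanceMatrix-class].
#' @param groups Categorical vector aligned with samples (2 levels for
#'   wilcoxon/kruskal_wallis).
#' @param method `"permanova"`, `"wilcoxon"` or `"kruskal_wallis"`.
#' @param n_perm Permutations for PERMANOVA.
#' @param seed RNG seed for PERMANOVA.
#' @return An `htest`-like result.
#' @export
betaDivTest <- function(D, groups,
                        method = c("permanova", "wilcoxon", "kruskal_wallis"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  if (method == "permanova") {
    if (is.null(seed)) stop_validation("permanova requires a seed")
    return(permanova(D, groups, n_perm = n_perm, seed = seed))
  }
  parts <- betaGroupDistances(D, groups)
  within <- c(parts$within_g1, parts$within_g2)
  between <- parts$between
  if (diff(range(c(within, between))) == 0) {
    # every pairwise distance identical: no separation is detectable
    return(structure(
      list(statistic = c(statistic = 0), p.value = 1,
           method = sprintf("%s on within- vs between-group distances (degenerate: all distances equal)",
                            method),
           data.name = "distance matrix"),
      class = "htest"))
  }
  if (method == "wilcoxon") {
    no_ties <- !any(duplicated(c(within, between)))
    use_exact <- length(within) <= 8L && length(between) <= 8L && no_ties
    stats::wilcox.test(between, within, exact = use_exact, correct = TRUE)
  } else {
    vals <- c(within, between)
    grp <- factor(rep(c("within", "between"), c(length(within), length(between))))
    stats::kruskal.test(vals, grp)
  }
}
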