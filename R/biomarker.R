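# Cross-validated biomarker selection: repeated stratified K-fold feature
# candidacy, importance-score thresholding, and CV ROC evaluation.

#' Repeated stratified K-fold cross-validation splits
#'
#' Within each repeat the samples are partitioned into K folds, stratified
#' so that each fold's class counts differ from the proportional share by
#' at most one sample per class. Deterministic under the seed.
#'
#' @param labels Two-level (or more) factor of class labels.
#' @param K Folds per repeat (each class must have at least K members).
#' @param N Number of repeats.
#' @param seed Integer RNG seed.
#' @return List of records, each `list(repeat_, fold, train, test)` with
#'   integer sample indices; folds partition the samples within a repeat.
#' @export
cvSplits <- function(labels, K, N, seed) {
  labels <- factor(labels)
  if (K < 2L) stop_validation("K must be at least 2")
  sizes <- table(labels)
  if (any(sizes < K)) {
    stop_validation(sprintf(
      "class '%s' has %d samples, fewer than K = %d folds",
      names(sizes)[which.min(sizes)], min(sizes), K))
  }
  n <- length(labels)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  out <- list()
  for (r in seq_len(N)) {
    fold_of <- integer(n)
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(K), length(idx))
    }
    for (k in seq_len(K)) {
      out[[length(out) + 1L]] <- list(
        repeat_ = r, fold = k,
        train = which(fold_of != k),
        test = which(fold_of == k)
      )
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

# ROC ----------------------------------------------------------------------

# Threshold-sweep ROC on predicted probabilities; y_pos logical.
roc_points <- function(prob, y_pos) {
  ts <- sort(unique(prob), decreasing = TRUE)
  tpr <- vapply(ts, function(t) mean(prob[y_pos] >= t), numeric(1))
  fpr <- vapply(ts, function(t) mean(prob[!y_pos] >= t), numeric(1))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
}

# Step-interpolate a fold ROC onto a fixed FPR grid (vertical averaging).
tpr_at_grid <- function(roc, grid) {
  stats::approx(roc$fpr, roc$tpr, xout = grid, method = "constant",
                f = 0, ties = max, rule = 2)$y
}

# Model fitting ------------------------------------------------------------

# Inverse-penalty grid for the L1 logistic path (8 points, 1e-3..1e3).
l1_c_grid <- function() 10^seq(-3, 3, length.out = 8)

fit_logistic_l1 <- function(x, y, seed) {
  n <- nrow(x)
  lambdas <- sort(1 / (n * l1_c_grid()), decreasing = TRUE)
  inner_k <- min(3L, min(table(y)))
  mean_auc <- rep(0, length(lambdas))
  if (inner_k >= 2L) {
    inner <- cvSplits(y, K = inner_k, N = 1L, seed = seed)
    n_used <- 0L
    for (sp in inner) {
      ytr <- y[sp$train]
      yte <- y[sp$test]
      if (nlevels(droplevels(ytr)) < 2L || nlevels(droplevels(yte)) < 2L) next
      fit <- glmnet::glmnet(x[sp$train, , drop = FALSE], ytr,
                            family = "binomial", alpha = 1, lambda = lambdas)
      prob <- stats::predict(fit, x[sp$test, , drop = FALSE], s = lambdas,
                             type = "response")
      pos <- yte == levels(y)[2L]
      for (j in seq_along(lambdas)) {
        rc <- roc_points(prob[, j], pos)
        mean_auc[j] <- mean_auc[j] + trapezoid_auc(rc$fpr, rc$tpr)
      }
      n_used <- n_used + 1L
    }
    if (n_used > 0L) mean_auc <- mean_auc / n_used
  }
  # ties broken toward the larger penalty (sparser model)
  best <- which(mean_auc >= max(mean_auc) - 1e-12)[1L]
  lambda <- lambdas[best]
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = lambdas)
  coefs <- as.matrix(stats::coef(fit, s = lambda))[-1L, 1L]
  list(
    importance = abs(coefs),
    candidates = names(coefs)[coefs != 0],
    predict = function(newx) {
      as.numeric(stats::predict(fit, newx, s = lambda, type = "response"))
    }
  )
}

fit_random_forest <- function(x, y, seed) {
  p <- ncol(x)
  grid <- unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), floor(p / 5))))
  set.seed(as.integer(seed))
  fits <- lapply(grid, function(m) {
    randomForest::randomForest(x, y, mtry = m, ntree = 300)
  })
  oob <- vapply(fits, function(f) f$err.rate[f$ntree, "OOB"], numeric(1))
  fit <- fits[[which.min(oob)]]
  imp <- randomForest::importance(fit)[, 1L]
  list(
    importance = imp,
    candidates = names(imp)[imp > 0],
    predict = function(newx) {
      stats::predict(fit, newx, type = "prob")[, levels(y)[2L]]
    }
  )
}

#' Per-fold biomarker candidates and fitted scorer
#'
#' `model = "logistic"` fits an L1-penalized logistic regression, with the
#' penalty strength chosen by an inner 3-fold grid search over a fixed
#' 8-point log-spaced grid (1e-3 to 1e3 in inverse-penalty units);
#' candidates are the features with nonzero coefficients.
#' `model = "random_forest"` fits a random forest with a grid over
#' features-per-split (sqrt(p), p/3, p/5) chosen by out-of-bag error;
#' candidates are features with positive impurity importance. In both
#' cases the candidate set is truncated to the top `candidate_fraction`
#' of features by importance when `candidate_fraction < 1`.
#'
#' @param x Training matrix, samples x features (logCPM scale).
#' @param y Two-level factor of training labels.
#' @param model `"logistic"` or `"random_forest"`.
#' @param candidate_fraction Fraction in (0, 1] of top features retained.
#' @param seed Integer RNG seed.
#' @return List with `candidates` (feature ids), `importance` (named
#'   scores used for truncation) and `predict` (probability scorer for the
#'   positive class, the second factor level).
#' @export
foldCandidates <- function(x, y, model = c("logistic", "random_forest"),
                           candidate_fraction = 1, seed = 1L) {
  model <- match.arg(model)
  y <- factor(y)
  if (nlevels(y) != 2L || any(table(y) < 2L)) {
    stop_validation("training fold needs 2 classes with >= 2 samples each")
  }
  fit <- if (model == "logistic") {
    fit_logistic_l1(x, y, seed)
  } else {
    fit_random_forest(x, y, seed)
  }
  if (candidate_fraction < 1) {
    n_keep <- max(1L, as.integer(round(candidate_fraction * ncol(x))))
    ranked <- names(sort(fit$importance, decreasing = TRUE))
    fit$candidates <- intersect(utils::head(ranked, n_keep), fit$candidates)
    if (!length(fit$candidates)) {
      fit$candidates <- utils::head(ranked, n_keep)
    }
  }
  fit
}

#' Importance scores from per-fold candidate sets
#'
#' The importance score of a feature is the fraction of non-skipped
#' cross-validation folds whose candidate set contained it.
#'
#' @param candidate_sets List of character vectors, one per non-skipped fold.
#' @param features All feature ids under consideration.
#' @return Named numeric vector of scores in \[0, 1\].
#' @export
scoreImportance <- function(candidate_sets, features) {
  if (!length(candidate_sets)) stop_validation("no non-skipped folds")
  counts <- vapply(features, function(f) {
    sum(vapply(candidate_sets, function(s) f %in% s, logical(1)))
  }, numeric(1))
  counts / length(candidate_sets)
}

#' Cross-validated biomarker identification
#'
#' Pipeline: aggregate to `level` (optional), transform to logCPM, run
#' N-repeat stratified K-fold cross-validation calling [foldCandidates()]
#' on each training fold, and score each feature by the fraction of
#' non-skipped folds whose candidate set contained it (the importance
#' score). Features with a score of at least `P` form the biomarker.
#'
#' The biomarker is then evaluated by a fresh repeated CV (same K and N,
#' offset seed) restricted to the selected features: the model (with its
#' hyperparameter grid search) is refit within each evaluation training
#' fold and scored on the held-out samples, so no held-out sample
#' influences any fitting step of its own fold. Per-fold ROC curves come
#' from a threshold sweep on predicted probabilities; the mean ROC is the
#' vertical average of the fold TPRs on a fixed 101-point FPR grid, and
#' the mean AUC the mean of per-fold trapezoidal AUCs.
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @param target Name of a two-level categorical covariate.
#' @param model `"logistic"` (default) or `"random_forest"`.
#' @param level Optional taxonomy rank to aggregate to.
#' @param K Folds per repeat (default 3).
#' @param N Repeats (default 3).
#' @param P Importance-score cutoff in \[0, 1\] (default 0.20).
#' @param candidate_fraction Per-fold top-fraction truncation in (0, 1\]
#'   (default 1: no truncation).
#' @param seed Integer RNG seed (mandatory).
#' @return A [BiomarkerResult-class].
#' @export
findBiomarker <- function(exp, target, model = c("logistic", "random_forest"),
                          level = NULL, K = 3L, N = 3L, P = 0.20,
                          candidate_fraction = 1, seed) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  model <- match.arg(model)
  if (missing(seed) || !is_number(seed)) {
    stop_validation("findBiomarker requires an integer seed")
  }
  if (!is_number(P) || P < 0 || P > 1) stop_validation("P must lie in [0, 1]")
  if (!is_number(candidate_fraction) || candidate_fraction <= 0 ||
      candidate_fraction > 1) {
    stop_validation("candidate_fraction must lie in (0, 1]")
  }
  if (!is.null(level)) exp <- upsampleCounts(exp, level)
  md <- sampleData(exp)
  if (!target %in% colnames(md)) {
    stop_validation(sprintf("unknown covariate '%s'", target))
  }
  y <- factor(md[[target]])
  if (nlevels(y) != 2L) stop_validation("target must have exactly 2 levels")
  if (length(y) < 30L) {
    warning("fewer than 30 samples: biomarker selection may overfit; ",
            "interpret with extreme caution", call. = FALSE)
  }
  x <- t(countsToLogCPM(meCounts(exp)))

  splits <- cvSplits(y, K = K, N = N, seed = seed)
  counts_in <- stats::setNames(numeric(ncol(x)), colnames(x))
  n_folds_used <- 0L
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    ytr <- droplevels(y[sp$train])
    if (nlevels(ytr) < 2L || any(table(ytr) < 2L)) {
      warning(sprintf("fold %d skipped: degenerate class distribution", i),
              call. = FALSE)
      next
    }
    cand <- foldCandidates(x[sp$train, , drop = FALSE], y[sp$train],
                           model = model,
                           candidate_fraction = candidate_fraction,
                           seed = as.integer(seed) + i)
    counts_in[cand$candidates] <- counts_in[cand$candidates] + 1
    n_folds_used <- n_folds_used + 1L
  }
  if (n_folds_used == 0L) stop_validation("all cross-validation folds skipped")
  importance <- counts_in / n_folds_used
  selected <- names(importance)[importance >= P & importance > 0]
  if (P == 0) selected <- names(importance)[importance > 0]
  if (!length(selected)) {
    stop_validation(sprintf(
      "no feature reaches importance cutoff P = %g; lower P", P))
  }

  # Evaluation on the fixed selected set, fresh folds, per-fold refits.
  eval_splits <- cvSplits(y, K = K, N = N, seed = as.integer(seed) + 1000L)
  grid <- seq(0, 1, by = 0.01)
  fold_auc <- numeric()
  tpr_mat <- NULL
  xs <- x[, selected, drop = FALSE]
  for (i in seq_along(eval_splits)) {
    sp <- eval_splits[[i]]
    ytr <- droplevels(y[sp$train])
    yte <- droplevels(y[sp$test])
    if (nlevels(ytr) < 2L || any(table(ytr) < 2L) || nlevels(yte) < 2L) next
    fit <- fit_eval_model(xs[sp$train, , drop = FALSE], y[sp$train], model,
                          seed = as.integer(seed) + 2000L + i)
    prob <- fit(xs[sp$test, , drop = FALSE])
    rc <- roc_points(prob, y[sp$test] == levels(y)[2L])
    fold_auc <- c(fold_auc, trapezoid_auc(rc$fpr, rc$tpr))
    tpr_mat <- rbind(tpr_mat, tpr_at_grid(rc, grid))
  }
  if (!length(fold_auc)) {
    stop_validation("no evaluation fold had both classes held out")
  }
  new("BiomarkerResult",
      selected = selected,
      importance = importance,
      fold_auc = fold_auc,
      mean_auc = mean(fold_auc),
      roc = data.frame(fpr = grid, mean_tpr = colMeans(tpr_mat)),
      config = list(target = target, model = model, level = level,
                    K = K, N = N, P = P,
                    candidate_fraction = candidate_fraction, seed = seed))
}

# Refit the chosen model for evaluation; single-feature logistic models use
# an unpenalized fit (the L1 grid search is meaningless at p = 1).
fit_eval_model <- function(x, y, model, seed) {
  y <- factor(y)
  if (model == "logistic" && ncol(x) == 1L) {
    df <- data.frame(y = y == levels(y)[2L], f = x[, 1L])
    fit <- suppressWarnings(stats::glm(y ~ f, data = df, family = stats::binomial()))
    function(newx) {
      as.numeric(stats::predict(fit, data.frame(f = newx[, 1L]),
                                type = "response"))
    }
  } else {
    foldCandidates(x, y, model = model, candidate_fraction = 1,
                   seed = seed)$predict
  }
}
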