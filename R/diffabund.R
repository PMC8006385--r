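# Differential abundance: NB-GLM Wald path and empirical-Bayes moderated-t
# path, plus per-group extended result columns.

#' Median-of-ratios size factors
#'
#' Zero-tolerant variant of the median-of-ratios normalization: the
#' per-feature geometric mean is computed over strictly positive counts
#' only, the per-sample factor is the median of count/geomean ratios over
#' features positive in that sample, and the factors are rescaled to
#' geometric mean 1.
#'
#' @param counts Numeric count matrix, features x samples.
#' @return Named numeric vector of size factors, geometric mean 1.
#' @export
#' @examples
#' m <- cbind(A = c(10, 20), B = c(20, 40))
#' rownames(m) <- c("f1", "f2")
#' medianRatioSizeFactors(m)  # (1/sqrt(2), sqrt(2))
medianRatioSizeFactors <- function(counts) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  logc <- log(counts)
  logc[!is.finite(logc)] <- NA
  geo <- exp(rowMeans(logc, na.rm = TRUE))  # positive counts only
  usable <- is.finite(geo) & geo > 0
  if (!any(usable)) {
    stop_validation("no feature with a positive count to normalize on")
  }
  sf <- vapply(seq_len(ncol(counts)), function(j) {
    r <- counts[usable, j] / geo[usable]
    r <- r[counts[usable, j] > 0]
    if (!length(r)) {
      stop_validation(sprintf(
        "sample '%s' shares no positive feature with the geometric reference",
        colnames(counts)[j]))
    }
    stats::median(r)
  }, numeric(1))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

# NB-Wald -----------------------------------------------------------------

# NB log-likelihood at dispersion alpha given a fitted mean vector.
nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# Fit the NB GLM for one feature at fixed dispersion alpha.
nb_glm_at_alpha <- function(y, X, off, alpha) {
  fam <- MASS::negative.binomial(theta = 1 / alpha, link = "log")
  suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = off,
                   control = stats::glm.control(maxit = 50))
  )
}

#' Per-feature negative-binomial Wald fits
#'
#' For each feature, fits a negative-binomial GLM with log link and
#' `log(size factor)` offsets on the supplied design matrix. The
#' dispersion (variance `mu + alpha*mu^2`) is estimated per feature by
#' profile maximum likelihood, started from a method-of-moments value and
#' bounded in `[1e-8, 10]`. The Wald statistic for the coefficient in
#' column `coef` is `beta / SE(beta)` with the standard error from the
#' Fisher information of the final IRLS fit; p values are two-sided
#' normal. Features whose IRLS did not converge (or whose estimate
#' diverged) are flagged and their p value set missing.
#'
#' @param counts Count matrix (features x samples).
#' @param design Design matrix (samples x coefficients), full rank, with
#'   intercept.
#' @param size_factors Per-sample normalization factors; default
#'   [medianRatioSizeFactors()].
#' @param coef Index of the coefficient to test (default 2, the first
#'   non-intercept column).
#' @return Data frame per feature: `beta` (natural-log scale), `se`, `z`,
#'   `p`, `alpha` (dispersion), `converged`.
#' @export
nbWaldFit <- function(counts, design, size_factors = NULL, coef = 2L) {
  stopifnot(is.matrix(counts), is.matrix(design),
            ncol(counts) == nrow(design))
  if (is.null(size_factors)) size_factors <- medianRatioSizeFactors(counts)
  off <- log(size_factors)
  res <- lapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    # method-of-moments start on normalized counts
    z <- y / size_factors
    mz <- mean(z)
    a0 <- if (mz > 0) (stats::var(z) - mz) / mz^2 else 0.1
    a0 <- min(max(a0, 1e-4), 10)
    opt <- tryCatch(
      stats::optimize(function(la) {
        a <- exp(la)
        fit <- nb_glm_at_alpha(y, design, off, a)
        # Cox-Reid adjusted profile likelihood: the 0.5*log|X'WX| term
        # removes the downward bias of the plain dispersion MLE (the NB
        # analogue of REML), keeping the Wald test calibrated.
        cr <- 0.5 * determinant(crossprod(design * sqrt(fit$weights)),
                                logarithm = TRUE)$modulus
        -(nb_loglik(y, fit$fitted.values, a) - as.numeric(cr))
      }, interval = log(c(1e-8, 10)), tol = 1e-4),
      error = function(e) NULL
    )
    if (is.null(opt)) {
      return(data.frame(beta = NA_real_, se = NA_real_, z = NA_real_,
                        p = NA_real_, alpha = NA_real_, converged = FALSE))
    }
    a_hat <- exp(opt$minimum)
    fit <- nb_glm_at_alpha(y, design, off, a_hat)
    beta <- fit$coefficients[coef]
    # Fisher information from the final IRLS weights
    w <- fit$weights
    xtx <- crossprod(design * sqrt(w))
    vc <- tryCatch(solve(xtx), error = function(e) NULL)
    se <- if (is.null(vc)) NA_real_ else sqrt(vc[coef, coef])
    conv <- isTRUE(fit$converged) && is.finite(beta) && is.finite(se) &&
      abs(beta) < 15 && se > 0
    zstat <- if (conv) beta / se else NA_real_
    data.frame(beta = unname(beta), se = unname(se), z = unname(zstat),
               p = if (conv) 2 * stats::pnorm(-abs(zstat)) else NA_real_,
               alpha = a_hat, converged = conv)
  })
  out <- do.call(rbind, res)
  rownames(out) <- rownames(counts)
  out
}

# Moderated t -------------------------------------------------------------

# Newton inversion of the trigamma function (monotone decreasing on the
# positive axis); used for the empirical-Bayes moment matching.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated t fits on a Gaussian response matrix
#'
#' Ordinary least squares of each feature (row of `Y`, typically logCPM)
#' on the design, followed by empirical-Bayes shrinkage of the residual
#' variances: the prior degrees of freedom `d0` and prior variance `s0^2`
#' are estimated by closed-form moment matching of `log(s_g^2)`
#' (digamma/trigamma inversion), the posterior variance is
#' `(d0*s0^2 + d*s_g^2) / (d0 + d)`, and the moderated t statistic
#' `beta / (s_tilde * sqrt(v))` is referred to a t distribution with
#' `d0 + d` degrees of freedom.
#'
#' `d0` may be fixed: `d0 = 0` reproduces the ordinary per-feature t test,
#' `d0 = Inf` pools all features to the common prior variance. If the
#' moment-matching fails (non-positive spread), `d0 = Inf` is used with a
#' warning.
#'
#' @param Y Response matrix, features x samples (e.g. logCPM).
#' @param design Design matrix (samples x coefficients) with intercept.
#' @param coef Coefficient column to test (default 2).
#' @param d0 Optional fixed prior degrees of freedom; `NULL` to estimate.
#' @return Data frame per feature: `beta`, `se` (posterior), `t`, `df`,
#'   `p`, plus attributes `d0` and `s0_sq`.
#' @export
moderatedTFit <- function(Y, design, coef = 2L, d0 = NULL) {
  stopifnot(is.matrix(Y), is.matrix(design), ncol(Y) == nrow(design))
  n <- ncol(Y)
  p <- ncol(design)
  d <- n - p
  if (d < 1L) stop_validation("no residual degrees of freedom")
  qr_x <- qr(design)
  if (qr_x$rank < p) stop_validation("design matrix is rank deficient")
  fit <- stats::lm.fit(design, t(Y))
  betas <- t(fit$coefficients)           # features x coefs
  resid <- t(fit$residuals)              # features x samples
  s2 <- rowSums(resid^2) / d
  v_coef <- chol2inv(qr.R(qr_x))[coef, coef]

  if (is.null(d0)) {
    pos <- s2 > 0
    if (sum(pos) < 2L) {
      warning("too few positive variances; using pooled variance (d0 = Inf)",
              call. = FALSE)
      d0 <- Inf
      s0_sq <- mean(s2)
    } else {
      z <- log(s2[pos])
      e <- z - digamma(d / 2) + log(d / 2)
      emean <- mean(e)
      evar <- sum((e - emean)^2) / (sum(pos) - 1L)
      rhs <- evar * sum(pos) / (sum(pos) - 1L) - trigamma(d / 2)
      if (is.finite(rhs) && rhs > 0) {
        d0 <- 2 * trigamma_inverse(rhs)
        s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
      } else {
        warning("variance spread at or below sampling noise; pooling (d0 = Inf)",
                call. = FALSE)
        d0 <- Inf
        s0_sq <- exp(emean)
      }
    }
  } else {
    s0_sq <- if (is.infinite(d0) || d0 > 0) {
      # prior variance from the same moment relation (or pooled when d0=Inf)
      if (is.infinite(d0)) mean(s2) else {
        zz <- log(s2[s2 > 0])
        exp(mean(zz) + digamma(d0 / 2) - log(d0 / 2))
      }
    } else 0
  }

  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_post * v_coef)
  tstat <- betas[, coef] / se
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  # d0 = 0 must reduce exactly to the ordinary t (df = d)
  if (!is.infinite(d0) && d0 == 0) df_total <- d
  pvals <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(beta = unname(betas[, coef]), se = unname(se),
                    t = unname(tstat), df = df_total, p = unname(pvals))
  rownames(out) <- rownames(Y)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

# Extended columns ---------------------------------------------------------

#' Per-group percentage, prevalence and size-adjusted fold change
#'
#' For a two-level target: `pct_g` is the mean relative abundance of the
#' feature over the samples of group g; `prev_g` the fraction of group-g
#' samples with a nonzero count; `adj_fc` the epsilon-stabilized ratio
#' `(pct_g1 + eps) / (pct_g2 + eps)` with `eps = 1e-6`, which stays finite
#' when a feature is absent from one group.
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @param target Name of a two-level categorical covariate.
#' @return Data frame per feature: `pct_group1`, `pct_group2`,
#'   `prev_group1`, `prev_group2`, `adj_fc`. Group 1 is the first factor
#'   level of the target.
#' @export
daExtendedColumns <- function(exp, target) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  md <- sampleData(exp)
  if (!target %in% colnames(md)) {
    stop_validation(sprintf("unknown covariate '%s'", target))
  }
  grp <- factor(md[[target]])
  if (nlevels(grp) != 2L) {
    stop_validation("target must have exactly 2 levels")
  }
  cts <- meCounts(exp)
  rel <- countsToRelabu(cts)
  g1 <- grp == levels(grp)[1L]
  g2 <- grp == levels(grp)[2L]
  eps <- 1e-6
  pct1 <- rowMeans(rel[, g1, drop = FALSE])
  pct2 <- rowMeans(rel[, g2, drop = FALSE])
  data.frame(
    pct_group1 = pct1,
    pct_group2 = pct2,
    prev_group1 = rowMeans(cts[, g1, drop = FALSE] > 0),
    prev_group2 = rowMeans(cts[, g2, drop = FALSE] > 0),
    adj_fc = (pct1 + eps) / (pct2 + eps),
    row.names = rownames(cts)
  )
}

# Top-level ----------------------------------------------------------------

#' Differential abundance between two sample groups
#'
#' Two model paths over the same interface. `"nb_wald"` fits per-feature
#' negative-binomial GLMs on raw counts with median-of-ratios offsets and
#' tests the group coefficient by a Wald test ([nbWaldFit()]).
#' `"moderated_t"` fits ordinary least squares on logCPM and shrinks the
#' residual variances by empirical Bayes ([moderatedTFit()]). Both report
#' `log2fc` oriented so that a positive value means higher abundance in
#' group 1 (the first factor level of the target), BH-adjusted p values,
#' and the extended per-group columns of [daExtendedColumns()].
#'
#' Features are tested only when their mean raw count across all samples
#' is at least `min_count`. Non-converged NB fits are flagged, their p set
#' missing and excluded from the BH denominator.
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @param target Name of a two-level categorical covariate.
#' @param method `"nb_wald"` or `"moderated_t"`.
#' @param level Optional taxonomy rank to aggregate to first.
#' @param covariates Optional character vector of adjustment covariates.
#' @param min_count Minimum mean raw count for a feature to be tested.
#' @param alpha Adjusted-p significance threshold echoed in the result
#'   attributes (used by reporting, not by the fit).
#' @return Data frame, one row per tested feature, ordered by p:
#'   `feature`, `log2fc`, `se`, `statistic`, `p`, `p_adj`, the extended
#'   columns, and `converged`.
#' @export
differentialAbundance <- function(exp, target,
                                  method = c("nb_wald", "moderated_t"),
                                  level = NULL, covariates = NULL,
                                  min_count = 1, alpha = 0.05) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  method <- match.arg(method)
  if (!is_number(min_count) || min_count < 0) {
    stop_validation("min_count must be a non-negative number")
  }
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_validation("alpha must lie in (0, 1)")
  }
  if (!is.null(level)) exp <- upsampleCounts(exp, level)
  md <- sampleData(exp)
  if (!target %in% colnames(md)) {
    stop_validation(sprintf("unknown covariate '%s'", target))
  }
  grp <- factor(md[[target]])
  if (nlevels(grp) != 2L) {
    stop_validation("target must have exactly 2 levels (recode multi-level factors first)")
  }
  bad_cov <- setdiff(covariates, colnames(md))
  if (length(bad_cov)) {
    stop_validation(sprintf("unknown covariate(s): %s",
                            paste(bad_cov, collapse = ", ")))
  }

  cts <- meCounts(exp)
  keep <- rowMeans(cts) >= min_count
  if (!any(keep)) stop_validation("no feature passes min_count")
  cts <- cts[keep, , drop = FALSE]

  # Indicator of group 1 (first level): positive log2fc = higher in group 1.
  x <- as.numeric(grp == levels(grp)[1L])
  dsgn <- data.frame(group1 = x)
  for (cv in covariates) dsgn[[cv]] <- md[[cv]]
  design <- stats::model.matrix(~ ., data = dsgn)

  if (method == "nb_wald") {
    fit <- nbWaldFit(cts, design, coef = 2L)
    log2fc <- fit$beta / log(2)
    se <- fit$se / log(2)
    statistic <- fit$z
    p <- fit$p
    converged <- fit$converged
  } else {
    lcpm <- countsToLogCPM(cts)
    fit <- moderatedTFit(lcpm, design, coef = 2L)
    log2fc <- fit$beta
    se <- fit$se
    statistic <- fit$t
    p <- fit$p
    converged <- rep(TRUE, nrow(fit))
  }

  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")

  ext <- daExtendedColumns(
    pickFeatures(exp, rownames(cts), mode = "keep"), target)
  out <- data.frame(feature = rownames(cts), log2fc = log2fc, se = se,
                    statistic = statistic, p = p, p_adj = p_adj,
                    ext[rownames(cts), ], converged = converged,
                    row.names = NULL)
  out <- out[order(out$p), ]
  attr(out, "method") <- method
  attr(out, "target") <- target
  attr(out, "group1") <- levels(grp)[1L]
  attr(out, "group2") <- levels(grp)[2L]
  attr(out, "alpha") <- alpha
  out
}
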