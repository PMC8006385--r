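# Permutational multivariate analysis of variance on a distance matrix.

# One-way pseudo-F for a given labelling. d2 is the squared-distance
# matrix; SS_T = sum_{i<j} d2_ij / N; SS_W = sum_g (1/n_g) sum_{i<j in g}
# d2_ij. For an indicator vector g, sum over pairs within the group equals
# (g' d2 g) / 2.
permanova_F <- function(d2, groups, ss_t) {
  levs <- levels(groups)
  a <- length(levs)
  n <- length(groups)
  ss_w <- 0
  for (l in levs) {
    idx <- groups == l
    ng <- sum(idx)
    if (ng > 1L) {
      ss_w <- ss_w + sum(d2[idx, idx]) / (2 * ng)
    }
  }
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

#' PERMANOVA: permutation test on a distance matrix
#'
#' One-way PERMANOVA. The total sum of squares is
#' `SS_T = sum_{i<j} d_ij^2 / N`, the within-group sum of squares
#' `SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, and the pseudo-F statistic
#' `F = ((SS_T - SS_W)/(a - 1)) / (SS_W/(N - a))` for `a` groups. The p
#' value is estimated by permuting group labels:
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`, which never returns 0.
#'
#' Groups of size 1 are permitted with a warning (their within-group term
#' is zero).
#'
#' @param D A [DistanceMatrix-class] (or plain symmetric matrix).
#' @param groups Categorical vector aligned with the samples, >= 2 levels.
#' @param n_perm Number of label permutations (default 999; a value below
#'   99 triggers a warning).
#' @param seed Integer RNG seed (mandatory: permutation results must be
#'   reproducible).
#' @return An `htest`-style list with `statistic` (pseudo-F), `p.value`,
#'   `parameter` (n_perm), `method`, and the sums of squares in `estimate`.
#' @export
permanova <- function(D, groups, n_perm = 999, seed) {
  d <- if (is(D, "DistanceMatrix")) D@dist else D
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (missing(seed) || !is_number(seed)) {
    stop_validation("permanova requires an integer seed")
  }
  groups <- factor(groups)
  groups <- droplevels(groups)
  n <- nrow(d)
  a <- nlevels(groups)
  if (length(groups) != n) {
    stop_validation("groups length must match the number of samples")
  }
  if (a < 2L) stop_validation("need at least 2 groups")
  if (n < a + 1L) stop_validation("need more samples than groups")
  if (any(table(groups) == 1L)) {
    warning("singleton group present: its within-group sum of squares is 0",
            call. = FALSE)
  }
  if (n_perm < 99) {
    warning("n_perm < 99 gives a coarse permutation p value", call. = FALSE)
  }
  d2 <- d^2
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (l in levels(groups)) {
    idx <- groups == l
    if (sum(idx) > 1L) ss_w <- ss_w + sum(d2[idx, idx]) / (2 * sum(idx))
  }
  f_obs <- permanova_F(d2, groups, ss_t)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    gp <- groups[sample.int(n)]
    if (permanova_F(d2, gp, ss_t) >= f_obs) n_ge <- n_ge + 1L
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  structure(
    list(statistic = c(pseudo.F = f_obs),
         p.value = (1 + n_ge) / (1 + n_perm),
         parameter = c(n_perm = n_perm, groups = a),
         estimate = c(SS_total = ss_t, SS_within = ss_w,
                      SS_between = ss_t - ss_w),
         method = "PERMANOVA (one-way, label permutation)",
         data.name = "distance matrix"),
    class = "htest"
  )
}
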