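# Synthetic microbiome experiments with known ground truth. Counts are
# negative-binomial around Dirichlet baseline compositions with log-normal
# library sizes; a chosen subset of taxa carries a multiplicative group
# effect.

rdirichlet1 <- function(k, concentration) {
  g <- stats::rgamma(k, shape = concentration, rate = 1)
  if (all(g == 0)) g <- rep(1, k)
  g / sum(g)
}

# Log-normal draws with the stated arithmetic mean and coefficient of
# variation (cv = 0 degenerates to the constant mean).
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

random_taxonomy <- function(n_taxa, n_phyla, n_genera, feature_ids) {
  phyla <- paste0("Phylum_", seq_len(n_phyla))
  genera <- paste0("Genus_", seq_len(n_genera))
  genus_phylum <- sample(phyla, n_genera, replace = TRUE)
  genus_of <- sample(seq_len(n_genera), n_taxa, replace = TRUE)
  data.frame(
    superkingdom = rep("Bacteria", n_taxa),
    phylum = genus_phylum[genus_of],
    genus = genera[genus_of],
    species = feature_ids,
    row.names = feature_ids
  )
}

#' Simulate a grouped microbiome experiment with known truth
#'
#' Baseline taxon proportions are drawn from a symmetric Dirichlet; a
#' fraction `prop_da` of taxa is designated differentially abundant and
#' their group-2 mean is multiplied by `2^-log2fc` (equivalently, group 1
#' is `2^log2fc`-fold higher), without renormalizing the remaining taxa so
#' the stated fold change stays interpretable. Counts are negative
#' binomial with mean `L_j * q_i * effect_ij` and variance
#' `mu + dispersion * mu^2`; library sizes `L_j` are log-normal with the
#' stated mean and coefficient of variation. Metadata carries the group
#' factor and one continuous nuisance covariate; the taxonomy assigns taxa
#' randomly to the stated number of genera and phyla. Everything is
#' determined by `seed`.
#'
#' @param n_per_group Integer pair: samples in group 1 and group 2.
#' @param n_taxa Number of taxa (>= 2).
#' @param prop_da Fraction of taxa differentially abundant, in \[0, 1).
#' @param log2fc True log2 fold change (group 1 over group 2) of DA taxa.
#' @param dispersion NB dispersion alpha (> 0).
#' @param libsize_mean Mean library size.
#' @param libsize_cv Coefficient of variation of library sizes (>= 0).
#' @param base_concentration Symmetric Dirichlet concentration for the
#'   baseline proportions.
#' @param taxonomy_shape Integer pair `(n_phyla, n_genera)`.
#' @param seed Integer RNG seed.
#' @return List with `experiment` (a [MicrobiomeExperiment-class]) and
#'   `truth` (list: `da_taxa`, `true_log2fc`, `baseline`, `groups`).
#' @export
simulateExperiment <- function(n_per_group = c(10L, 10L), n_taxa = 100L,
                               prop_da = 0, log2fc = 2, dispersion = 0.2,
                               libsize_mean = 1e5, libsize_cv = 0.3,
                               base_concentration = 0.5,
                               taxonomy_shape = c(4L, 20L), seed) {
  if (missing(seed) || !is_number(seed)) {
    stop_validation("simulateExperiment requires an integer seed")
  }
  if (length(n_per_group) != 2L || any(n_per_group < 2L)) {
    stop_validation("n_per_group must be two integers >= 2")
  }
  if (n_taxa < 2L) stop_validation("n_taxa must be >= 2")
  if (prop_da < 0 || prop_da >= 1) stop_validation("prop_da must lie in [0, 1)")
  if (dispersion <= 0) stop_validation("dispersion must be positive")
  if (length(taxonomy_shape) != 2L || any(taxonomy_shape < 1L)) {
    stop_validation("taxonomy_shape must be (n_phyla, n_genera)")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  n1 <- n_per_group[1L]
  n2 <- n_per_group[2L]
  n <- n1 + n2
  feature_ids <- sprintf("taxon_%03d", seq_len(n_taxa))
  sample_ids <- sprintf("sample_%03d", seq_len(n))
  groups <- factor(rep(c("g1", "g2"), c(n1, n2)), levels = c("g1", "g2"))

  q <- rdirichlet1(n_taxa, base_concentration)
  n_da <- round(prop_da * n_taxa)
  da_idx <- if (n_da > 0) sort(sample.int(n_taxa, n_da)) else integer()

  lib <- rlnorm_mean_cv(n, libsize_mean, libsize_cv)
  effect <- matrix(1, n_taxa, n)
  if (n_da > 0) effect[da_idx, groups == "g2"] <- 2^(-log2fc)
  mu <- outer(q, lib) * effect
  cts <- matrix(stats::rnbinom(n_taxa * n, mu = mu, size = 1 / dispersion),
                n_taxa, n, dimnames = list(feature_ids, sample_ids))
  storage.mode(cts) <- "double"
  # guard: keep every sample's library positive so transforms are defined
  zero_cols <- colSums(cts) == 0
  if (any(zero_cols)) cts[which.max(q), zero_cols] <- 1

  tax <- random_taxonomy(n_taxa, taxonomy_shape[1L], taxonomy_shape[2L],
                         feature_ids)
  md <- data.frame(group = groups,
                   age = round(stats::rnorm(n, 40, 12), 1),
                   row.names = sample_ids)
  expmt <- MicrobiomeExperiment(cts, taxonomy = tax, metadata = md)
  list(
    experiment = expmt,
    truth = list(
      da_taxa = feature_ids[da_idx],
      true_log2fc = stats::setNames(rep(log2fc, length(da_idx)),
                                    feature_ids[da_idx]),
      baseline = stats::setNames(q, feature_ids),
      groups = stats::setNames(as.character(groups), sample_ids)
    )
  )
}

#' Simulate two groups with block community structure
#'
#' Both groups draw negative-binomial counts around group-specific
#' baseline compositions. Group 2's baseline is the group-1 baseline
#' perturbed taxon-wise by `exp(divergence * z)`, `z ~ N(0, 1)`, then
#' renormalized: `divergence = 0` makes the groups exchangeable (the null
#' construction for PERMANOVA calibration), larger values push the
#' expected between-group Bray-Curtis distance above the within-group
#' distances.
#'
#' @inheritParams simulateExperiment
#' @param divergence Non-negative scale of the between-group composition
#'   perturbation.
#' @return List with `experiment` and `truth` (baselines per group, group
#'   labels, divergence).
#' @export
simulateTwoClusterProfiles <- function(n_per_group = c(10L, 10L),
                                       n_taxa = 50L, divergence = 1,
                                       dispersion = 0.2,
                                       libsize_mean = 1e5, libsize_cv = 0.3,
                                       base_concentration = 0.5,
                                       taxonomy_shape = c(4L, 20L), seed) {
  if (missing(seed) || !is_number(seed)) {
    stop_validation("simulateTwoClusterProfiles requires an integer seed")
  }
  if (divergence < 0) stop_validation("divergence must be >= 0")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  n1 <- n_per_group[1L]
  n2 <- n_per_group[2L]
  n <- n1 + n2
  feature_ids <- sprintf("taxon_%03d", seq_len(n_taxa))
  sample_ids <- sprintf("sample_%03d", seq_len(n))
  groups <- factor(rep(c("g1", "g2"), c(n1, n2)), levels = c("g1", "g2"))

  q1 <- rdirichlet1(n_taxa, base_concentration)
  q2 <- q1 * exp(divergence * stats::rnorm(n_taxa))
  q2 <- q2 / sum(q2)

  lib <- rlnorm_mean_cv(n, libsize_mean, libsize_cv)
  qmat <- cbind(q1)[, rep(1L, n)]
  qmat[, groups == "g2"] <- q2
  mu <- qmat * rep(lib, each = n_taxa)
  cts <- matrix(stats::rnbinom(n_taxa * n, mu = mu, size = 1 / dispersion),
                n_taxa, n, dimnames = list(feature_ids, sample_ids))
  storage.mode(cts) <- "double"
  zero_cols <- colSums(cts) == 0
  if (any(zero_cols)) cts[which.max(q1), zero_cols] <- 1

  tax <- random_taxonomy(n_taxa, taxonomy_shape[1L], taxonomy_shape[2L],
                         feature_ids)
  md <- data.frame(group = groups,
                   age = round(stats::rnorm(n, 40, 12), 1),
                   row.names = sample_ids)
  expmt <- MicrobiomeExperiment(cts, taxonomy = tax, metadata = md)
  list(
    experiment = expmt,
    truth = list(baseline_g1 = stats::setNames(q1, feature_ids),
                 baseline_g2 = stats::setNames(q2, feature_ids),
                 groups = stats::setNames(as.character(groups), sample_ids),
                 divergence = divergence)
  )
}
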