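test_that("alpha diversity matches closed forms and direct evaluation", {
  uni <- make_me(matrix(c(3, 3, 3, 3), 4, 1,
                        dimnames = list(paste0("t", 1:4), "S")))
  expect_equal(alphaDiversity(uni, "shannon")[["S"]], log(4))
  expect_equal(alphaDiversity(uni, "gini_simpson")[["S"]], 0.75)
  expect_equal(alphaDiversity(uni, "inverse_simpson")[["S"]], 4)
  expect_equal(alphaDiversity(uni, "richness")[["S"]], 4)

  one <- make_me(matrix(c(9, 0), 2, 1, dimnames = list(c("a", "b"), "S")))
  expect_equal(alphaDiversity(one, "shannon")[["S"]], 0)
  expect_equal(alphaDiversity(one, "gini_simpson")[["S"]], 0)
  expect_equal(alphaDiversity(one, "inverse_simpson")[["S"]], 1)
  expect_equal(alphaDiversity(one, "richness")[["S"]], 1)

  # brute-force -sum(p log p) for counts (1,2,3)
  m <- make_me(matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("t", 1:3), "S")))
  p <- c(1, 2, 3) / 6
  expect_equal(alphaDiversity(m, "shannon")[["S"]], -sum(p * log(p)))
})

test_that("shannon and inverse-simpson respect their richness bounds", {
  for (seed in 1:5) {
    sim <- simulateExperiment(n_per_group = c(3, 3), n_taxa = 40,
                              prop_da = 0, seed = seed)
    sh <- alphaDiversity(sim$experiment, "shannon")
    rich <- alphaDiversity(sim$experiment, "richness")
    inv <- alphaDiversity(sim$experiment, "inverse_simpson")
    expect_true(all(sh <= log(rich) + 1e-12))
    expect_true(all(inv <= rich + 1e-12))
  }
})

test_that("wilcoxon exact p matches full enumeration of rank assignments", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c("a", "b"), each = 3)
  res <- alphaDivTest(vals, grp, method = "wilcoxon")

  # oracle: enumerate all C(6,3) = 20 assignments of ranks to group a,
  # two-sided p = fraction with rank-sum at least as extreme
  combos <- utils::combn(6, 3)
  sums <- colSums(matrix(vals[combos], nrow = 3))
  obs <- sum(vals[grp == "a"])
  center <- 3 * 7 / 2
  p_exact <- mean(abs(sums - center) >= abs(obs - center))
  expect_equal(p_exact, 0.1)
  expect_equal(res$p.value, p_exact)

  # no separation: symmetric identical groups
  same <- alphaDivTest(c(1, 2, 3, 1, 2, 3), grp, method = "kruskal_wallis")
  expect_equal(unname(same$statistic), 0)

  welch <- alphaDivTest(vals, grp, method = "t_test")
  expect_identical(welch$method, "Welch Two Sample t-test")

  expect_error(alphaDivTest(vals, rep(c("a", "b", "c"), 2), "wilcoxon"),
               class = "mbkit_validation_error")
  expect_error(alphaDivTest(c(1, 2), c("a", "b"), "t_test"),
               class = "mbkit_validation_error")
})

test_that("kruskal-wallis H equals z^2 of the untied rank-sum statistic", {
  set.seed(42)
  vals <- sample(1:20)  # tie-free
  grp <- rep(c("a", "b"), each = 10)
  H <- unname(alphaDivTest(vals, grp, "kruskal_wallis")$statistic)
  w <- stats::wilcox.test(vals[grp == "a"], vals[grp == "b"],
                          exact = FALSE, correct = FALSE)
  n1 <- n2 <- 10
  z <- (unname(w$statistic) - n1 * n2 / 2) /
    sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-10)
})

test_that("beta distances match hand evaluation and the vegan oracle", {
  m <- cbind(S1 = c(6, 4, 0), S2 = c(2, 4, 8))
  rownames(m) <- paste0("t", 1:3)
  bc <- distMatrix(betaDistance(m, "bray_curtis", assay = "counts"))
  expect_equal(bc["S1", "S2"], 0.5)
  jc <- distMatrix(betaDistance(m, "jaccard"))
  expect_equal(jc["S1", "S2"], 1 - 2 / 3)

  ident <- cbind(A = c(1, 2), B = c(1, 2))
  rownames(ident) <- c("x", "y")
  expect_equal(distMatrix(betaDistance(ident, "bray_curtis",
                                       assay = "counts"))["A", "B"], 0)
  expect_equal(distMatrix(betaDistance(ident, "jaccard"))["A", "B"], 0)

  disj <- cbind(A = c(3, 0), B = c(0, 5))
  rownames(disj) <- c("x", "y")
  expect_equal(distMatrix(betaDistance(disj, "bray_curtis",
                                       assay = "counts"))["A", "B"], 1)
  expect_equal(distMatrix(betaDistance(disj, "jaccard"))["A", "B"], 1)

  # vegan cross-check on 100 random non-degenerate count vectors
  set.seed(7)
  for (i in 1:50) {
    x <- matrix(rpois(8 * 4, 3) + (i %% 3 == 0), 8, 4,
                dimnames = list(paste0("f", 1:8), paste0("s", 1:4)))
    x[, colSums(x) == 0][1, ] <- 1
    ours_bc <- distMatrix(betaDistance(x, "bray_curtis", assay = "counts"))
    ref_bc <- as.matrix(vegan::vegdist(t(x), method = "bray"))
    expect_equal(unname(ours_bc), unname(ref_bc), tolerance = 1e-12)
    ours_j <- distMatrix(betaDistance(x, "jaccard"))
    ref_j <- as.matrix(vegan::vegdist(t(x), method = "jaccard",
                                      binary = TRUE))
    expect_equal(unname(ours_j), unname(ref_j), tolerance = 1e-12)
  }
})

test_that("betaGroupDistances partitions the strict upper triangle by pair type", {
  d <- matrix(0.3, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  diag(d) <- 0
  D <- new("DistanceMatrix", dist = d, metric = "bray_curtis")
  parts <- betaGroupDistances(D, c("a", "a", "b", "b"))
  # pair counting: C(2,2) = 1 within each group, 2*2 = 4 between
  expect_length(parts$within_g1, 1L)
  expect_length(parts$within_g2, 1L)
  expect_length(parts$between, 4L)
  expect_true(all(unlist(parts[1:3]) == 0.3))

  # permuting sample order leaves the multisets unchanged
  perm <- c(3, 1, 4, 2)
  Dp <- new("DistanceMatrix", dist = d[perm, perm], metric = "bray_curtis")
  pp <- betaGroupDistances(Dp, c("b", "a", "b", "a"))
  expect_equal(sort(pp$between), sort(parts$between))

  expect_error(betaGroupDistances(D, c("a", "b", "c", "a")),
               class = "mbkit_validation_error")
})

test_that("betaDivTest ranks between- vs within-group distances", {
  # block-structured distances: within 0.1, between 0.9
  g <- rep(c("a", "b"), each = 4)
  d <- outer(g, g, function(x, y) ifelse(x == y, 0.1, 0.9))
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  D <- new("DistanceMatrix", dist = d, metric = "bray_curtis")
  wt <- betaDivTest(D, g, method = "wilcoxon")
  expect_lt(wt$p.value, 0.05)

  # all-equal distances: massive ties, no separation
  d2 <- matrix(0.5, 8, 8, dimnames = dimnames(d))
  diag(d2) <- 0
  De <- new("DistanceMatrix", dist = d2, metric = "bray_curtis")
  expect_gt(betaDivTest(De, g, method = "wilcoxon")$p.value, 0.9)

  # permanova delegation reproduces permanova() exactly under the seed
  sim <- simulateTwoClusterProfiles(n_per_group = c(4, 4), n_taxa = 20,
                                    divergence = 1, seed = 3)
  Ds <- betaDistance(sim$experiment, "bray_curtis")
  grp <- sampleData(sim$experiment)$group
  a <- betaDivTest(Ds, grp, method = "permanova", n_perm = 199, seed = 9)
  b <- permanova(Ds, grp, n_perm = 199, seed = 9)
  expect_identical(a$p.value, b$p.value)
  expect_identical(a$statistic, b$statistic)
})

test_that("distance matrices round-trip through square TSV", {
  sim <- simulateTwoClusterProfiles(n_per_group = c(3, 3), n_taxa = 15,
                                    divergence = 0.5, seed = 2)
  D <- betaDistance(sim$experiment, "bray_curtis")
  f <- tempfile(fileext = ".tsv")
  writeDistanceMatrix(D, f)
  back <- readDistanceMatrix(f)
  expect_equal(distMatrix(back), distMatrix(D), tolerance = 1e-15)
  expect_identical(distMetric(back), "bray_curtis")
})
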