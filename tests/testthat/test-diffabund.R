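test_that("median-of-ratios size factors match hand evaluation", {
  m <- matrix(c(10, 20, 10, 20), 2, 2,
              dimnames = list(c("f1", "f2"), c("A", "B")))
  expect_equal(medianRatioSizeFactors(m), c(A = 1, B = 1))

  m2 <- matrix(c(10, 20, 20, 40), 2, 2,
               dimnames = list(c("f1", "f2"), c("A", "B")))
  expect_equal(medianRatioSizeFactors(m2),
               c(A = 1 / sqrt(2), B = sqrt(2)), tolerance = 1e-12)

  # single feature: factor ratio equals count ratio
  m1 <- matrix(c(4, 16), 1, 2, dimnames = list("f", c("A", "B")))
  sf <- medianRatioSizeFactors(m1)
  expect_equal(sf[["B"]] / sf[["A"]], 4)
})

test_that("extended columns give group percentages, prevalence and adj FC", {
  # group1 relabu of f: (0.2, 0.4); group2: (0.1, 0.1) -> pct 0.3 vs 0.1
  cts <- rbind(f = c(2, 4, 1, 1), other = c(8, 6, 9, 9))
  colnames(cts) <- paste0("S", 1:4)
  md <- data.frame(grp = c("g1", "g1", "g2", "g2"), row.names = colnames(cts))
  ext <- daExtendedColumns(make_me(cts, metadata = md), "grp")
  expect_equal(ext["f", "pct_group1"], 0.3)
  expect_equal(ext["f", "pct_group2"], 0.1)
  expect_equal(ext["f", "adj_fc"], (0.3 + 1e-6) / (0.1 + 1e-6))

  # identical groups: adj_fc = 1
  cts_eq <- rbind(f = c(3, 3, 3, 3), g = c(7, 7, 7, 7))
  colnames(cts_eq) <- paste0("S", 1:4)
  ext_eq <- daExtendedColumns(make_me(cts_eq, metadata = md), "grp")
  expect_equal(ext_eq$adj_fc, c(1, 1))

  # absent in group 2: prevalence 0, large but finite adj_fc
  cts_ab <- rbind(f = c(5, 5, 0, 0), g = c(5, 5, 10, 10))
  colnames(cts_ab) <- paste0("S", 1:4)
  ext_ab <- daExtendedColumns(make_me(cts_ab, metadata = md), "grp")
  expect_equal(ext_ab["f", "prev_group2"], 0)
  expect_true(is.finite(ext_ab["f", "adj_fc"]))
  expect_gt(ext_ab["f", "adj_fc"], 1e4)
})

test_that("moderated t reduces to the ordinary t at d0 = 0 and pools at d0 = Inf", {
  set.seed(21)
  Y <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(paste0("f", 1:60), NULL))
  X <- cbind(1, rep(c(1, 0), each = 5))

  fit0 <- moderatedTFit(Y, X, d0 = 0)
  # ordinary two-sample equal-variance t per feature
  for (i in c(1, 30, 60)) {
    tt <- stats::t.test(Y[i, 1:5], Y[i, 6:10], var.equal = TRUE)
    expect_equal(unname(fit0$t[i]), unname(tt$statistic), tolerance = 1e-10)
    expect_equal(fit0$p[i], tt$p.value, tolerance = 1e-10)
  }

  fitInf <- moderatedTFit(Y, X, d0 = Inf)
  expect_equal(stats::var(fitInf$se), 0, tolerance = 1e-24)  # shared variance
})

test_that("moderated t agrees with the limma oracle on estimated hyperparameters", {
  set.seed(5)
  s2_true <- stats::rchisq(200, df = 5) / 5
  Y <- matrix(rnorm(200 * 12, sd = rep(sqrt(s2_true), 12)), 200, 12)
  X <- cbind(1, rep(c(1, 0), each = 6))
  ours <- moderatedTFit(Y, X)
  lf <- limma::lmFit(Y, X)
  eb <- limma::eBayes(lf)
  expect_equal(attr(ours, "d0"), eb$df.prior, tolerance = 0.02)
  expect_equal(attr(ours, "s0_sq"), eb$s2.prior, tolerance = 0.02)
  expect_equal(ours$t, unname(eb$t[, 2]), tolerance = 0.01)
})

test_that("null moderated-t p values are uniform", {
  set.seed(77)
  Y <- matrix(rnorm(500 * 20), 500, 20,
              dimnames = list(paste0("f", 1:500), NULL))
  X <- cbind(1, rep(c(1, 0), each = 10))
  fit <- moderatedTFit(Y, X)
  ks <- stats::ks.test(fit$p, "punif")
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("NB-Wald log2fc sign follows the normalized group means", {
  sim <- simulateExperiment(n_per_group = c(10, 10), n_taxa = 40,
                            prop_da = 0.2, log2fc = 3, dispersion = 0.2,
                            seed = 31)
  me <- sim$experiment
  da <- differentialAbundance(me, "group", method = "nb_wald", min_count = 1)
  cts <- meCounts(me)
  sf <- medianRatioSizeFactors(cts)
  norm <- sweep(cts, 2, sf, "/")
  grp <- sampleData(me)$group
  m1 <- rowMeans(norm[, grp == "g1"])
  m2 <- rowMeans(norm[, grp == "g2"])
  conv <- da[da$converged & abs(m1 - m2)[match(da$feature, rownames(cts))] > 1e-9, ]
  expect_true(all(sign(conv$log2fc) ==
                  sign((m1 - m2)[match(conv$feature, rownames(cts))])))
})

test_that("both DA paths test the same features and broadly agree in ranking", {
  sim <- simulateExperiment(n_per_group = c(15, 15), n_taxa = 80,
                            prop_da = 0.15, log2fc = 2.5, dispersion = 0.1,
                            libsize_mean = 2e5, seed = 8)
  me <- sim$experiment
  nb <- differentialAbundance(me, "group", method = "nb_wald", min_count = 5)
  mt <- differentialAbundance(me, "group", method = "moderated_t",
                              min_count = 5)
  expect_setequal(nb$feature, mt$feature)

  shared <- intersect(nb$feature[!is.na(nb$p)], mt$feature)
  rho <- stats::cor(-log10(nb$p[match(shared, nb$feature)]),
                    -log10(mt$p[match(shared, mt$feature)]),
                    method = "spearman")
  expect_gte(rho, 0.8)

  # BH monotonicity: adjusted p never below raw p
  expect_true(all(nb$p_adj >= nb$p - 1e-15, na.rm = TRUE))
  expect_true(all(mt$p_adj >= mt$p - 1e-15, na.rm = TRUE))

  # adjustment matches the reference implementation
  ok <- !is.na(nb$p)
  expect_equal(nb$p_adj[ok], stats::p.adjust(nb$p[ok], "BH"))
})

test_that("differentialAbundance validates its configuration", {
  me <- toy_me()
  expect_error(differentialAbundance(me, "nonexistent"),
               class = "mbkit_validation_error")
  expect_error(differentialAbundance(me, "group", min_count = -1),
               class = "mbkit_validation_error")
  expect_error(differentialAbundance(me, "group", alpha = 2),
               class = "mbkit_validation_error")
  md3 <- sampleData(me)
  md3$group <- c("a", "b", "c", "a")
  me3 <- make_me(meCounts(me), metadata = md3)
  expect_error(differentialAbundance(me3, "group"), "2 levels",
               class = "mbkit_validation_error")
})
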