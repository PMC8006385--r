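test_that("cvSplits stratifies, partitions and is deterministic", {
  y <- factor(rep(c("a", "b"), each = 9))
  splits <- cvSplits(y, K = 3, N = 2, seed = 4)
  expect_length(splits, 6L)
  for (sp in splits) {
    # 9+9 with K=3: every fold holds exactly 3 of each class
    expect_equal(as.vector(table(y[sp$test])), c(3, 3))
    expect_setequal(c(sp$train, sp$test), seq_along(y))
    expect_length(intersect(sp$train, sp$test), 0L)
  }
  # folds of one repeat partition the samples
  rep1_tests <- lapply(splits[1:3], `[[`, "test")
  expect_setequal(unlist(rep1_tests), seq_along(y))

  expect_identical(cvSplits(y, K = 3, N = 2, seed = 4), splits)
  expect_false(identical(cvSplits(y, K = 3, N = 2, seed = 5), splits))

  expect_error(cvSplits(factor(c("a", "a", "a", "b", "b")), K = 3, N = 1,
                        seed = 1),
               class = "mbkit_validation_error")
})

test_that("importance scores count candidate-set membership", {
  sets <- c(rep(list(c("f1", "f2")), 2), rep(list("f1"), 7))
  sc <- scoreImportance(sets, c("f1", "f2", "f3"))
  expect_equal(sc[["f1"]], 1.0)
  expect_equal(sc[["f2"]], 2 / 9)
  expect_equal(sc[["f3"]], 0.0)
  # conservation: scores sum to total candidate count / fold count
  expect_equal(sum(sc), (2 * 2 + 7 * 1) / 9)
  expect_error(scoreImportance(list(), "f1"),
               class = "mbkit_validation_error")
})

test_that("a perfectly separating feature dominates fold candidacy", {
  set.seed(2)
  n <- 30
  p <- 20
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  y <- factor(rep(c("a", "b"), each = n / 2))
  x[, "f1"] <- ifelse(y == "b", 8, 0) + rnorm(n, sd = 0.5)

  hits <- 0L
  splits <- cvSplits(y, K = 3, N = 3, seed = 7)
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    cand <- foldCandidates(x[sp$train, ], y[sp$train], model = "logistic",
                           seed = 100 + i)
    if ("f1" %in% cand$candidates) hits <- hits + 1L
  }
  expect_gte(hits / length(splits), 0.9)
})

test_that("L1 candidacy stays sparse under permuted labels", {
  set.seed(10)
  n <- 30
  p <- 40
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  y <- factor(sample(rep(c("a", "b"), each = n / 2)))
  sizes <- integer()
  splits <- cvSplits(y, K = 3, N = 2, seed = 3)
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    cand <- foldCandidates(x[sp$train, ], y[sp$train], model = "logistic",
                           seed = 200 + i)
    sizes <- c(sizes, length(cand$candidates))
  }
  expect_lt(mean(sizes), p / 2)
})

test_that("candidate_fraction truncation forces the candidate-set size", {
  set.seed(6)
  n <- 20
  p <- 10
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  y <- factor(rep(c("a", "b"), each = n / 2))
  cand <- foldCandidates(x, y, model = "random_forest",
                         candidate_fraction = 1 / p, seed = 9)
  expect_length(cand$candidates, 1L)
})

test_that("findBiomarker selects the separating taxon and is bit-deterministic", {
  sim <- simulateExperiment(n_per_group = c(15, 15), n_taxa = 40,
                            prop_da = 1 / 40, log2fc = 6, dispersion = 0.2,
                            seed = 17)
  me <- sim$experiment
  target_taxon <- sim$truth$da_taxa
  expect_length(target_taxon, 1L)

  res <- suppressWarnings(findBiomarker(me, "group", model = "logistic",
                                        seed = 23))
  expect_true(target_taxon %in% selectedFeatures(res))
  expect_gte(importanceScores(res)[[target_taxon]], 0.9)
  expect_gte(meanAUC(res), 0.95)
  # importance scores are multiples of 1/(N*K) when no fold is skipped
  expect_equal(importanceScores(res) * 9, round(importanceScores(res) * 9),
               tolerance = 1e-12)

  res2 <- suppressWarnings(findBiomarker(me, "group", model = "logistic",
                                         seed = 23))
  expect_identical(selectedFeatures(res), selectedFeatures(res2))
  expect_identical(importanceScores(res), importanceScores(res2))
  expect_identical(foldAUC(res), foldAUC(res2))
  expect_identical(rocCurve(res), rocCurve(res2))

  # P = 0 keeps every feature that appeared in any candidate set
  res0 <- suppressWarnings(findBiomarker(me, "group", model = "logistic",
                                         P = 0, seed = 23))
  imp <- importanceScores(res0)
  expect_setequal(selectedFeatures(res0), names(imp)[imp > 0])

  # below 30 samples the small-sample caveat is surfaced
  sub24 <- pickSamples(me, sampleIds(me)[1:24], mode = "keep")
  expect_warning(findBiomarker(sub24, "group", model = "logistic", seed = 23),
                 "caution")
})

test_that("an unreachable importance cutoff advises lowering P", {
  # permuted labels: no taxon can appear in (nearly) all candidate sets
  sim <- simulateExperiment(n_per_group = c(12, 12), n_taxa = 30,
                            prop_da = 0, seed = 71)
  me <- sim$experiment
  set.seed(72)
  md <- sampleData(me)
  md$group <- sample(md$group)
  me <- MicrobiomeExperiment(meCounts(me), taxonomy = taxonomyTable(me),
                             metadata = md)
  expect_error(suppressWarnings(
    findBiomarker(me, "group", model = "logistic", P = 0.95, seed = 73)),
    "lower P", class = "mbkit_validation_error")
})

test_that("evaluation ROC machinery is internally consistent", {
  # known probabilities: AUC computable by hand
  prob <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  pos <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  rc <- mbkit:::roc_points(prob, pos)
  # oracle: probability a positive outranks a negative (no ties)
  pairs <- expand.grid(p = prob[pos], n = prob[!pos])
  expect_equal(mbkit:::trapezoid_auc(rc$fpr, rc$tpr),
               mean(pairs$p > pairs$n))
  grid <- seq(0, 1, by = 0.01)
  tpr <- mbkit:::tpr_at_grid(rc, grid)
  expect_length(tpr, 101L)
  expect_true(all(diff(tpr) >= 0))
  expect_equal(tpr[101], 1)
})
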