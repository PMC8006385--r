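test_that("relative abundance and logCPM follow their formulas", {
  m <- matrix(c(2, 3, 5, 7, 0, 0), 3, 2,
              dimnames = list(paste0("f", 1:3), c("A", "B")))
  rel <- countsToRelabu(m)
  expect_equal(unname(rel[, "A"]), c(0.2, 0.3, 0.5))
  expect_equal(colSums(rel), c(A = 1, B = 1), tolerance = 1e-12)

  single <- matrix(7, 1, 1, dimnames = list("f", "S"))
  expect_equal(unname(countsToRelabu(single)[1, 1]), 1.0)

  zero <- matrix(c(1, 0), 1, 2, dimnames = list("f", c("ok", "empty")))
  expect_error(countsToRelabu(zero), "empty",
               class = "mbkit_validation_error")
  expect_error(countsToLogCPM(zero), "empty",
               class = "mbkit_validation_error")

  lc <- countsToLogCPM(m)
  expect_equal(lc["f3", "B"], 0)                       # zero count -> 0
  expect_equal(unname(countsToLogCPM(single)[1, 1]), log2(1e6 + 1))
  # scale invariance: doubling a column leaves logCPM unchanged
  m2 <- m; m2[, "A"] <- m[, "A"] * 2
  expect_equal(countsToLogCPM(m2)[, "A"], lc[, "A"])
  expect_true(all(lc >= 0))
  expect_identical(lc == 0, m == 0)
})

test_that("upsampleCounts sums within level labels and conserves totals", {
  me <- toy_me()  # sp1, sp2 share GenA; sp3 is GenB
  g <- upsampleCounts(me, "genus")
  expect_identical(featureIds(g), c("GenA", "GenB"))
  expect_equal(meCounts(g)["GenA", ], colSums(meCounts(me)[c("sp1", "sp2"), ]))
  expect_equal(colSums(meCounts(g)), colSums(meCounts(me)))
  # taxonomy truncated to ranks at or above genus
  expect_identical(colnames(taxonomyTable(g)), c("phylum", "genus"))

  # finest rank with unique labels: permutation of the input counts
  sp <- upsampleCounts(me, "species")
  expect_equal(meCounts(sp)[featureIds(me), ], meCounts(me))

  # unclassified labels aggregate into the "unclassified" feature
  tax <- taxonomyTable(me)
  tax$genus <- c("GenA", unclassifiedMarker(), unclassifiedMarker())
  me2 <- make_me(meCounts(me), taxonomy = tax, metadata = sampleData(me))
  g2 <- upsampleCounts(me2, "genus")
  expect_true(unclassifiedMarker() %in% featureIds(g2))
  expect_equal(meCounts(g2)[unclassifiedMarker(), ],
               colSums(meCounts(me)[c("sp2", "sp3"), ]))

  no_tax <- make_me(meCounts(me), metadata = sampleData(me))
  expect_error(upsampleCounts(no_tax, "genus"), "absent",
               class = "mbkit_validation_error")
  expect_error(upsampleCounts(me, "ordnung"), "unknown rank",
               class = "mbkit_validation_error")
})

test_that("conservation of column sums holds across simulated experiments", {
  for (seed in 1:5) {
    sim <- simulateExperiment(n_per_group = c(3, 3), n_taxa = 30,
                              prop_da = 0, seed = seed)
    me <- sim$experiment
    for (lvl in c("phylum", "genus")) {
      up <- upsampleCounts(me, lvl)
      expect_identical(colSums(meCounts(up)), colSums(meCounts(me)))
    }
  }
})

test_that("filterFeatures applies AND-conjoined criteria and reports removals", {
  cts <- matrix(c(10, 1, 0, 0,
                  20, 0, 0, 0,
                  30, 2, 5, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("half", "rare", "common"),
                                paste0("S", 1:4)))
  me <- make_me(cts)
  # prevalence oracle: "rare" present in 1/4 samples < 0.5
  flt <- filterFeatures(me, min_prevalence = 0.5)
  expect_false("rare" %in% featureIds(flt))
  expect_true(all(c("half", "common") %in% featureIds(flt)))
  rep <- filterReport(flt)
  expect_identical(rep$feature_id, "rare")
  expect_identical(rep$criterion, "min_prevalence")

  # all-zero spec is the identity
  id <- filterFeatures(me)
  expect_identical(meCounts(id), meCounts(me))

  # explicit discard wins regardless of thresholds
  ex <- filterFeatures(me, explicit_discard = "common")
  expect_false("common" %in% featureIds(ex))

  # idempotence: same spec twice equals once
  once <- filterFeatures(me, min_avg_reads = 2, min_prevalence = 0.5)
  twice <- filterFeatures(once, min_avg_reads = 2, min_prevalence = 0.5)
  expect_identical(meCounts(twice), meCounts(once))

  expect_error(filterFeatures(me, min_avg_reads = 1e9), "all features",
               class = "mbkit_validation_error")
})

test_that("filterSamples supports equality, range and id predicates", {
  me <- toy_me()
  eq <- filterSamples(me, covariate = "group", values = "case")
  expect_identical(sampleIds(eq), c("S1", "S2"))
  expect_identical(rownames(sampleData(eq)), c("S1", "S2"))

  # unbounded range on a continuous covariate is the identity
  rng <- filterSamples(me, covariate = "age", range = c(-Inf, Inf))
  expect_identical(meCounts(rng), meCounts(me))

  expect_error(filterSamples(me, covariate = "group", values = "zebra"),
               "no samples", class = "mbkit_validation_error")
  expect_error(filterSamples(me, covariate = "nope", values = "x"),
               "unknown covariate", class = "mbkit_validation_error")
})

test_that("categorizeCovariate bins by quantile or explicit breakpoints", {
  b <- categorizeCovariate(1:10, n_bins = 2)
  expect_equal(as.vector(table(b$factor)), c(5, 5))

  # explicit breakpoints honoured verbatim: [0,5) holds 1..4
  eb <- categorizeCovariate(1:10, breaks = c(0, 5, 10))
  expect_equal(as.vector(table(eb$factor)), c(4, 6))
  expect_identical(eb$labels, c("[0,5)", "[5,10]"))

  expect_error(categorizeCovariate(rep(3, 5), n_bins = 2), "constant",
               class = "mbkit_validation_error")
  expect_error(categorizeCovariate(letters, n_bins = 2),
               class = "mbkit_validation_error")
  expect_error(categorizeCovariate(1:10, breaks = c(5, 5)),
               "degenerate", class = "mbkit_validation_error")
})
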