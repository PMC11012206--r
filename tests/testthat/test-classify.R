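test_that("stratified 70/30 split of the study cohort yields 157/68", {
  d <- generateBlock(syntheticConfig(seed = 10), "mir")
  sp <- splitTrainTest(d, splitSpec(seed = 1))
  expect_identical(nSamples(sp$train), 157L)
  expect_identical(nSamples(sp$test), 68L)
  # per-class allocation: floors + remainders to largest fractional parts
  expect_identical(
    as.integer(table(sampleLabels(sp$train))),
    c(31L, 32L, 34L, 31L, 29L)
  )
  # disjoint and exhaustive
  expect_identical(
    sort(c(sampleIds(sp$train), sampleIds(sp$test))),
    sort(sampleIds(d))
  )
})

test_that("splits are seed-reproducible and stratification stays within one sample", {
  d <- generateBlock(smallConfig(seed = 1), "uv")
  s1 <- splitTrainTest(d, splitSpec(seed = 9))
  s2 <- splitTrainTest(d, splitSpec(seed = 9))
  s3 <- splitTrainTest(d, splitSpec(seed = 10))
  expect_identical(s1$trainIdx, s2$trainIdx)
  expect_false(identical(s1$trainIdx, s3$trainIdx))
  shares <- table(sampleLabels(s1$train)) / table(sampleLabels(d))
  expect_true(all(abs(shares - 0.7) <= 1 / min(table(sampleLabels(d)))))
})

test_that("every family fits a separable toy perfectly and predicts its labels", {
  d <- toySeparable(n_per_class = 8)
  for (fam in c("svc", "rf", "ann", "gbt")) {
    m <- trainClassifier(classifierSpec(fam, seed = 2), d)
    expect_equal(accuracyOf(m, d), 100, info = fam)
    expect_identical(
      as.character(predict(m, d)),
      as.character(sampleLabels(d)),
      info = fam
    )
  }
})

test_that("unknown hyperparameters and degenerate training sets are rejected", {
  expect_error(classifierSpec("rf", trees = 10), "unknown hyperparameter")
  expect_error(classifierSpec("svc", hidden = 5), "unknown hyperparameter")
  d <- toySeparable()
  oneClass <- d[sampleLabels(d) == "A", ]
  expect_error(trainClassifier(classifierSpec("rf"), oneClass), "2 classes")
})

test_that("prediction rejects width mismatches and is row-equivariant", {
  d <- toySeparable(n_per_class = 8, p = 6)
  m <- trainClassifier(classifierSpec("rf", seed = 1), d)
  expect_error(predict(m, matrix(0, 2, 3)), "width")
  perm <- c(5, 1, 9, 2)
  predAll <- predict(m, d)
  predPerm <- predict(m, intensities(d)[perm, ])
  expect_identical(as.character(predPerm), as.character(predAll)[perm])
})

test_that("masked models accept full-width input and apply the stored mask", {
  d <- toySeparable(n_per_class = 8, p = 6)
  mask <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  m <- trainClassifier(classifierSpec("svc", seed = 1), d, mask = mask)
  expect_identical(m@featureCount, 2L)
  predFull <- predict(m, d) # full width, mask applied internally
  predMasked <- predict(m, intensities(d)[, mask])
  expect_identical(predFull, predMasked)
  expect_error(predict(m, matrix(0, 2, 4)), "width")
})

test_that("model fits are reproducible from the spec seed", {
  d <- generateBlock(smallConfig(seed = 2), "uv")
  sp <- splitTrainTest(d, splitSpec(seed = 3))
  for (fam in c("rf", "ann", "gbt")) {
    p1 <- predict(trainClassifier(classifierSpec(fam, seed = 7), sp$train), sp$test)
    p2 <- predict(trainClassifier(classifierSpec(fam, seed = 7), sp$train), sp$test)
    expect_identical(p1, p2, info = fam)
  }
})

test_that("random forests do not generalize beyond their training fit on noise", {
  # train on pure noise: training accuracy (in-sample) should on average
  # exceed held-out accuracy, the overfitting direction
  gap <- vapply(1:10, function(seed) {
    withr::with_seed(seed, {
      x <- matrix(rnorm(60 * 10), 60, 10)
      lab <- rep(c("A", "B"), 30)
    })
    d <- SpectralDataset(x,
      axis = (1:10) * 10, units = "nm",
      sampleIds = sprintf("N%02d", 1:60), labels = lab
    )
    sp <- splitTrainTest(d, splitSpec(seed = seed))
    m <- trainClassifier(classifierSpec("rf", numTrees = 100L, seed = seed), sp$train)
    accuracyOf(m, sp$train) - accuracyOf(m, sp$test)
  }, numeric(1L))
  expect_gt(mean(gap), 0)
})
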