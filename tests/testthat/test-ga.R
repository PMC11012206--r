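test_that("feature masks require at least one selected variable", {
  expect_error(featureMask(rep(FALSE, 5)), "at least one")
  m <- featureMask(c(TRUE, FALSE, TRUE))
  expect_identical(m$selectedCount, 2L)
  expect_error(
    maskFitness(rep(FALSE, 4), toySeparable(), gaConfig()),
    "at least one"
  )
})

test_that("fitness is 1 on a separable toy and near chance on pure noise", {
  d <- toySeparable(n_per_class = 10)
  cfg <- gaConfig(
    cvFolds = 2L, parsimonyLambda = 0,
    baseClassifier = classifierSpec("rf", numTrees = 100L), seed = 3
  )
  f <- maskFitness(featureMask(c(TRUE, FALSE, FALSE, FALSE)), d, cfg)
  expect_equal(f, 1.0)

  noise <- withr::with_seed(8, {
    SpectralDataset(matrix(rnorm(40 * 6), 40, 6),
      axis = 1:6 * 10, units = "nm",
      labels = rep(c("A", "B"), 20)
    )
  })
  fn <- mean(vapply(1:5, function(s) {
    maskFitness(featureMask(rep(TRUE, 6)), noise, gaConfig(
      cvFolds = 2L, parsimonyLambda = 0, seed = s,
      baseClassifier = classifierSpec("rf", numTrees = 100L)
    ))
  }, numeric(1L)))
  expect_lt(abs(fn - 0.5), 0.15)
})

test_that("fitness applies the parsimony penalty and is seed-deterministic", {
  d <- toySeparable(n_per_class = 10)
  cfg <- gaConfig(
    cvFolds = 2L, parsimonyLambda = 0.1,
    baseClassifier = classifierSpec("rf", numTrees = 50L), seed = 5
  )
  cfg0 <- cfg
  cfg0$parsimonyLambda <- 0
  fSmall <- maskFitness(featureMask(c(TRUE, FALSE, FALSE, FALSE)), d, cfg)
  fBig <- maskFitness(featureMask(rep(TRUE, 4)), d, cfg)
  # the single separating variable gives CV accuracy 1, penalized by 1/4 bits
  expect_equal(fSmall, 1 - 0.1 * 1 / 4)
  # penalty identity: lambda * fraction selected, on top of the raw accuracy
  expect_equal(fBig, maskFitness(featureMask(rep(TRUE, 4)), d, cfg0) - 0.1)
  expect_identical(maskFitness(featureMask(rep(TRUE, 4)), d, cfg), fBig)
})

test_that("ga matches exhaustive search on a small deterministic instance", {
  p <- 8L
  f <- ruggedFitness(p = p, seed = 7)
  best <- exhaustiveBest(f, p)
  hits <- vapply(1:5, function(seed) {
    res <- gaSelect(p, gaConfig(
      populationSize = 30L, generations = 60L, patience = 60L, seed = seed
    ), fitnessFun = f)
    abs(f(res$mask$bits) - best$fitness) < 1e-12
  }, logical(1L))
  expect_gte(mean(hits), 0.8)
})

test_that("ga runs are reproducible and elitism makes best fitness non-decreasing", {
  f <- ruggedFitness(p = 10, seed = 9)
  cfg <- gaConfig(populationSize = 20L, generations = 25L, patience = 25L, seed = 4)
  r1 <- gaSelect(10L, cfg, fitnessFun = f)
  r2 <- gaSelect(10L, cfg, fitnessFun = f)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$history$bestFitness, r2$history$bestFitness)
  expect_true(all(diff(r1$history$bestFitness) >= 0))
  expect_identical(
    length(r1$history$selectionFrequency), 10L
  )
  expect_true(all(r1$history$selectionFrequency >= 0 &
    r1$history$selectionFrequency <= 1))
})

test_that("all-zero chromosomes are repaired to exactly one set bit", {
  # init density so small that zero masks occur constantly
  res <- gaSelect(6L, gaConfig(
    populationSize = 12L, generations = 3L, initDensity = 1e-9,
    mutationProbPerBit = 0, patience = 3L, seed = 2
  ), fitnessFun = function(bits) sum(bits) * 0.01)
  expect_gte(res$mask$selectedCount, 1L)
  # the initial population consists of repaired single-bit masks: the best
  # fitness of generation 1 must equal 0.01
  expect_equal(res$history$bestFitness[1L], 0.01)
})

test_that("ga recovers informative windows on the small split-signal cohort", {
  # raw blocks: off-peak columns are pure baseline + noise there, so the
  # informative windows are genuinely privileged (SNV would spread class
  # signal into every column through the per-spectrum sd)
  inWinRate <- vapply(1:3, function(seed) {
    cfg <- smallConfig(seed = seed)
    pr <- generatePaired(cfg)
    fu <- llfuse(list(mir = pr$mir, uv = pr$uv))
    res <- gaSelect(fu, gaConfig(
      populationSize = 14L, generations = 10L, patience = 10L, cvFolds = 3L,
      initDensity = 0.1,
      baseClassifier = classifierSpec("rf", numTrees = 60L), seed = seed
    ))
    w <- informativeWindows(cfg)
    axMir <- spectralAxis(pr$mir)
    axUv <- spectralAxis(pr$uv)
    inside <- c(
      axMir >= w$mir[1, "lo"] & axMir <= w$mir[1, "hi"],
      axUv >= w$uv[1, "lo"] & axUv <= w$uv[1, "hi"]
    )
    freq <- res$history$selectionFrequency
    mean(freq[inside]) - mean(freq[!inside])
  }, numeric(1L))
  expect_gt(mean(inWinRate), 0)
})

test_that("invalid GA configurations are rejected", {
  expect_error(gaConfig(populationSize = 1), "populationSize")
  expect_error(gaConfig(populationSize = 5, elitismCount = 5), "elitismCount")
  expect_error(gaConfig(initDensity = 0), "initDensity")
  expect_error(gaConfig(cvFolds = 1), "cvFolds")
})
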