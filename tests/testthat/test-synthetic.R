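test_that("default configuration reproduces the study design", {
  cfg <- syntheticConfig()
  expect_identical(cfg$classSizes, c(45L, 46L, 48L, 44L, 42L))
  expect_identical(sum(cfg$classSizes), 225L)
  uv <- generateBlock(cfg, "uv")
  mir <- generateBlock(cfg, "mir")
  expect_identical(dim(intensities(uv)), c(225L, 511L))
  expect_identical(dim(intensities(mir)), c(225L, 361L))
  expect_identical(axisUnits(uv), "nm")
  expect_identical(axisUnits(mir), "cm-1")
  expect_identical(
    as.integer(table(sampleLabels(uv))),
    c(45L, 46L, 48L, 44L, 42L)
  )
})

test_that("identical seeds give bit-identical blocks, different seeds differ", {
  a <- generateBlock(smallConfig(seed = 11), "uv")
  b <- generateBlock(smallConfig(seed = 11), "uv")
  c <- generateBlock(smallConfig(seed = 12), "uv")
  expect_identical(intensities(a), intensities(b))
  expect_false(identical(intensities(a), intensities(c)))
})

test_that("noise-free, effect-free spectra collapse to the shared backbone", {
  cfg <- smallConfig(
    scatterSigma = 0, offsetSigma = 0, slopeSigma = 0,
    ampJitterSigma = 0, noiseSigma = 0,
    uvPeaks = list(peakSpec(230, 12, 0.5, c(0, 0, 0))),
    mirPeaks = list(peakSpec(1300, 60, 0.5, c(0, 0, 0)))
  )
  x <- intensities(generateBlock(cfg, "uv"))
  expect_true(all(abs(sweep(x, 2L, x[1L, ])) < 1e-12))
})

test_that("noise-free class differences equal the offset-weighted peak shapes", {
  cfg <- smallConfig(
    scatterSigma = 0, offsetSigma = 0, slopeSigma = 0,
    ampJitterSigma = 0, noiseSigma = 0
  )
  d <- generateBlock(cfg, "uv")
  x <- intensities(d)
  lab <- sampleLabels(d)
  t <- spectralAxis(d)
  # closed form: class 3 minus class 1 = 0.3 * gaussian(230, width 12)
  diffObserved <- x[which(lab == "C3")[1L], ] - x[which(lab == "C1")[1L], ]
  diffExpected <- 0.3 * exp(-(t - 230)^2 / (2 * 12^2))
  expect_equal(diffObserved, diffExpected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("paired blocks share IDs, labels and row order", {
  pr <- generatePaired(smallConfig(seed = 5))
  expect_identical(sampleIds(pr$uv), sampleIds(pr$mir))
  expect_identical(sampleLabels(pr$uv), sampleLabels(pr$mir))
  expect_identical(nSamples(pr$uv), 30L)
  # independent noise between blocks: intensities must differ
  expect_false(identical(intensities(pr$uv), intensities(pr$mir)))
})

test_that("default paired config is the split-signal preset with declared windows", {
  w <- informativeWindows(syntheticConfig())
  expect_gt(nrow(w$uv), 0L)
  expect_gt(nrow(w$mir), 0L)
  # informative peaks divided between the blocks
  expect_true(all(w$uv[, "lo"] < w$uv[, "hi"]))
  expect_true(all(w$mir[, "lo"] >= 400) && all(w$uv[, "hi"] <= 700 + 100))
  # zero-effect preset declares no informative windows at all
  wz <- informativeWindows(zeroEffectConfig())
  expect_identical(nrow(wz$uv), 0L)
  expect_identical(nrow(wz$mir), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(peakSpec(250, width = 0, baseAmplitude = 1, classOffsets = 0), "width")
  expect_error(
    peakSpec(250, width = 1, baseAmplitude = 0.1, classOffsets = c(-0.5, 0)),
    "negative"
  )
  expect_error(syntheticConfig(nClasses = 3, classSizes = c(5, 5)), "classSizes")
  expect_error(
    syntheticConfig(uvPeaks = list(peakSpec(250, 10, 1, c(0, 0)))),
    "classOffsets"
  )
  expect_error(smallConfig(uvAxis = c(200, 300, 500)), "2 points")
})

test_that("raising noise does not raise accuracy of a fixed classifier", {
  diffs <- vapply(1:10, function(seed) {
    accAt <- function(noise) {
      cfg <- smallConfig(seed = seed, noiseSigma = noise)
      pr <- generatePaired(cfg)
      fu <- llfuse(list(mir = snv(pr$mir), uv = snv(pr$uv)))
      sp <- splitTrainTest(fu, splitSpec(seed = seed))
      m <- trainClassifier(classifierSpec("svc", seed = 1), sp$train)
      accuracyOf(m, sp$test)
    }
    accAt(0.01) - accAt(1.5)
  }, numeric(1L))
  # same seed -> the large-noise cohort shares every non-noise draw, so the
  # comparison is paired; averaged over seeds the clean cohort cannot lose
  expect_gte(mean(diffs), 0)
})
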