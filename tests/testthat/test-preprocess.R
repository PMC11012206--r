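mkDataset <- function(x) {
  SpectralDataset(x,
    axis = seq(100, by = 10, length.out = ncol(x)),
    units = "nm", labels = rep("a", nrow(x))
  )
}

test_that("snv matches the closed-form values and row identities", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1),
    ignore_attr = TRUE
  )
  expect_equal(
    snv(matrix(c(1, 2, 4), 1)),
    matrix(c(-0.8729, -0.2182, 1.0911), 1),
    tolerance = 1e-4, ignore_attr = TRUE
  )
  withr::with_seed(1, {
    x <- matrix(rnorm(20 * 50), 20, 50)
  })
  z <- snv(x)
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
})

test_that("snv is invariant to positive affine transforms of each spectrum", {
  withr::with_seed(2, {
    x <- matrix(rnorm(10 * 30), 10, 30)
    a <- rnorm(10)
    b <- exp(rnorm(10))
  })
  expect_equal(snv(a + b * x), snv(x), tolerance = 1e-9)
  expect_equal(snv(matrix(2 + 3 * c(1, 2, 4), 1)), snv(matrix(c(1, 2, 4), 1)),
    tolerance = 1e-12
  )
})

test_that("snv rejects zero-variance spectra naming the sample", {
  d <- mkDataset(rbind(c(1, 2, 3), c(5, 5, 5)))
  expect_error(snv(d), "S2")
})

test_that("msc reproduces the hand-computed least-squares correction", {
  ref <- c(0, 1, 2)
  out <- msc(matrix(c(1, 3, 6), 1), reference = ref)
  expect_equal(out, matrix(c(0.0667, 0.8667, 2.0667), 1),
    tolerance = 1e-4, ignore_attr = TRUE
  )
  # independent oracle: coefficients from lm()
  fit <- lm(c(1, 3, 6) ~ ref)
  expect_equal(as.numeric(out), (c(1, 3, 6) - coef(fit)[1]) / coef(fit)[2])
})

test_that("msc exactly recovers affinely distorted spectra and fixes identity", {
  withr::with_seed(3, {
    ref <- rnorm(40)
    a <- rnorm(8)
    b <- rnorm(8, mean = 2)
  })
  x <- a + outer(b, ref)
  out <- msc(x, reference = ref)
  expect_lt(max(abs(sweep(out, 2, ref))), 1e-9)
  expect_equal(msc(matrix(ref, 1), reference = ref), matrix(ref, 1),
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("msc default reference is the mean spectrum; degenerate slopes error", {
  withr::with_seed(4, x <- matrix(rnorm(6 * 20), 6, 20))
  expect_equal(msc(x), msc(x, reference = colMeans(x)))
  d <- mkDataset(rbind(c(0, 1, 2, 3), c(3, 2, 1, 0)))
  # second spectrum has slope -1 against itself... use orthogonal spectrum
  dd <- mkDataset(rbind(c(0, 1, 2, 3), c(1, -1, -1, 1)))
  expect_error(msc(dd, reference = c(0, 1, 2, 3)), "S2")
})

test_that("sg smoothing preserves low-order polynomials and interpolates at full order", {
  tt <- seq_len(31)
  x <- matrix(3 + 0.5 * tt - 0.2 * tt^2, 1)
  sm <- sgSmooth(x, window = 5, polyorder = 2)
  expect_equal(sm[1, 3:29], x[1, 3:29], tolerance = 1e-9)
  withr::with_seed(5, y <- matrix(rnorm(15), 1))
  expect_equal(sgSmooth(y, window = 5, polyorder = 4), y, tolerance = 1e-9)
})

test_that("sg window 3 / order 1 equals the mirror-padded moving mean", {
  x <- matrix(c(1, 10, 1, 10, 1), 1)
  expect_equal(sgSmooth(x, window = 3, polyorder = 1),
    matrix(c(7, 4, 7, 4, 7), 1),
    ignore_attr = TRUE
  )
})

test_that("sg agrees with a direct polynomial-fit oracle and is linear", {
  withr::with_seed(6, {
    x <- rnorm(25)
    y <- rnorm(25)
  })
  for (case in list(c(5, 2), c(7, 3), c(9, 0))) {
    expect_equal(
      as.numeric(sgSmooth(matrix(x, 1), case[1], case[2])),
      sgOracle(x, case[1], case[2]),
      tolerance = 1e-8
    )
  }
  lhs <- sgSmooth(matrix(2 * x - 3 * y, 1), 7, 2)
  rhs <- 2 * sgSmooth(matrix(x, 1), 7, 2) - 3 * sgSmooth(matrix(y, 1), 7, 2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("sg rejects invalid window/order combinations", {
  x <- matrix(rnorm(20), 1)
  expect_error(sgSmooth(x, window = 4, polyorder = 1), "odd")
  expect_error(sgSmooth(x, window = 5, polyorder = 5), "polyorder")
  expect_error(sgSmooth(x, window = 25, polyorder = 2), "exceeds")
})

test_that("applyPreprocess freezes the msc reference from the training partition", {
  cfg <- smallConfig(seed = 9)
  d <- generateBlock(cfg, "uv")
  sp <- splitTrainTest(d, splitSpec(seed = 1))
  res <- applyPreprocess(preprocessSpec("msc"), sp$train, sp$test)
  expect_equal(res$mscReference, colMeans(intensities(sp$train)))
  # test rows must not affect the reference: perturb test, reference unchanged
  testPerturbed <- sp$test
  res2 <- applyPreprocess(preprocessSpec("msc"), sp$train, testPerturbed[1:5, ])
  expect_identical(res$mscReference, res2$mscReference)
  expect_identical(
    intensities(res$train),
    intensities(applyPreprocess(preprocessSpec("msc"), sp$train, NULL)$train)
  )
})

test_that("preprocessing with scatter-dominated spectra improves accuracy", {
  delta <- vapply(1:10, function(seed) {
    cfg <- smallConfig(seed = seed, scatterSigma = 0.6, noiseSigma = 0.002)
    d <- generateBlock(cfg, "uv")
    sp <- splitTrainTest(d, splitSpec(seed = seed))
    accFor <- function(tf) {
      tr <- tf(sp$train)
      te <- tf(sp$test)
      accuracyOf(trainClassifier(classifierSpec("svc", seed = 1), tr), te)
    }
    accFor(snv) - accFor(identity)
  }, numeric(1L))
  expect_gte(mean(delta), 0)
})
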