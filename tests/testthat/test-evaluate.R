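test_that("a hand-countable toy yields the documented confusion and metrics", {
  r <- evaluateLabels(c("A", "A", "B"), c("A", "B", "B"))
  cm <- confusionMatrix(r)
  # rows = predicted, columns = true
  expect_identical(cm["A", ], c(A = 1L, B = 0L))
  expect_identical(cm["B", ], c(A = 1L, B = 1L))
  expect_equal(accuracy(r), 200 / 3)
  pc <- perClassMetrics(r)
  expect_identical(pc$FN[pc$class == "A"], 1L)
  expect_identical(pc$FP[pc$class == "B"], 1L)
  expect_equal(pc$precision, c(1, 0.5))
  expect_equal(pc$recall, c(0.5, 1))
})

test_that("perfect prediction gives a diagonal matrix and 100% accuracy", {
  lab <- factor(rep(c("Yunnan", "Shandong", "Henan", "Anhui", "Jiangsu"),
    times = c(17, 14, 13, 12, 12)
  ))
  r <- evaluateLabels(lab, lab)
  cm <- confusionMatrix(r)
  expect_identical(sum(cm) - sum(diag(cm)), 0L)
  expect_equal(accuracy(r), 100)
  # a class with 17 correct and no off-diagonal mass has precision = recall = 1
  pc <- perClassMetrics(r)
  expect_identical(pc$TP[pc$class == "Yunnan"], 17L)
  expect_equal(pc$precision[pc$class == "Yunnan"], 1)
  expect_equal(pc$recall[pc$class == "Yunnan"], 1)
})

test_that("count identities hold on random label vectors", {
  withr::with_seed(11, {
    for (i in 1:5) {
      k <- sample(2:5, 1)
      n <- sample(20:60, 1)
      classes <- LETTERS[1:k]
      truth <- sample(classes, n, replace = TRUE)
      pred <- sample(classes, n, replace = TRUE)
      r <- evaluateLabels(truth, pred, classOrder = classes)
      cm <- confusionMatrix(r)
      pc <- perClassMetrics(r)
      expect_identical(sum(cm), n)
      expect_equal(accuracy(r), 100 * sum(diag(cm)) / n)
      expect_identical(pc$FP, as.integer(rowSums(cm) - diag(cm)))
      expect_identical(pc$FN, as.integer(colSums(cm) - diag(cm)))
      expect_true(all(pc$TP + pc$TN + pc$FP + pc$FN == n))
      # self-evaluation has zero off-diagonal mass
      expect_identical(
        sum(confusionMatrix(evaluateLabels(truth, truth, classes))),
        sum(diag(confusionMatrix(evaluateLabels(truth, truth, classes))))
      )
    }
  })
})

test_that("permuting the class order permutes the matrix and keeps accuracy", {
  truth <- c("a", "b", "c", "a", "b", "c", "c")
  pred <- c("a", "c", "c", "b", "b", "a", "c")
  r1 <- evaluateLabels(truth, pred, classOrder = c("a", "b", "c"))
  r2 <- evaluateLabels(truth, pred, classOrder = c("c", "a", "b"))
  expect_equal(accuracy(r1), accuracy(r2))
  expect_identical(
    confusionMatrix(r1)[c("c", "a", "b"), c("c", "a", "b")],
    confusionMatrix(r2)
  )
})

test_that("labels outside the class order and length mismatches error", {
  expect_error(evaluateLabels(c("a", "x"), c("a", "a"), classOrder = c("a", "b")), "x")
  expect_error(evaluateLabels(c("a", "b"), c("a")), "length")
})

test_that("text rendering is deterministic with two-decimal accuracy", {
  r <- evaluateLabels(c("A", "A", "B"), c("A", "B", "B"))
  txt <- reportToText(r)
  expect_true(any(grepl("accuracy: 66.67", txt, fixed = TRUE)))
  expect_identical(txt, reportToText(r))
})

test_that("an empty class reports NaN precision/recall, never 0 or 1", {
  r <- evaluateLabels(c("A", "A"), c("A", "A"), classOrder = c("A", "B"))
  pc <- perClassMetrics(r)
  expect_true(is.nan(pc$precision[pc$class == "B"]))
  expect_true(is.nan(pc$recall[pc$class == "B"]))
  expect_true(any(grepl("NaN", reportToText(r))))
})

test_that("the transpose flag flips to the rows-as-true convention", {
  truth <- c("A", "A", "B")
  pred <- c("A", "B", "B")
  r <- evaluateLabels(truth, pred)
  rt <- evaluateLabels(truth, pred, transpose = TRUE)
  expect_identical(confusionMatrix(rt), t(confusionMatrix(r)))
  expect_equal(accuracy(rt), accuracy(r))
})
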