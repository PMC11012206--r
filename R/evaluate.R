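#' Confusion-matrix evaluation
#'
#' Builds the confusion matrix in the rows-as-predicted convention (rows are
#' predicted classes, columns are true classes; the diagonal counts correct
#' predictions), the overall accuracy in percent, and per-class TP/TN/FP/FN
#' with precision and recall. Under this convention `FP_c` is the row-c sum
#' minus the diagonal and `FN_c` the column-c sum minus the diagonal.
#' Precision or recall with a zero denominator is `NaN`.
#'
#' @param trueLabels,predictedLabels equal-length label vectors
#' @param classOrder character vector fixing row/column order; defaults to
#'   the union of factor levels (or observed values) of both inputs in order
#'   of appearance
#' @param transpose if `TRUE` the returned matrix uses the transposed
#'   (rows = true) convention; all derived metrics are unchanged
#' @return an [EvaluationReport-class]
#' @export
#' @examples
#' r <- evaluateLabels(c("A", "A", "B"), c("A", "B", "B"))
#' confusionMatrix(r)
#' accuracy(r)
evaluateLabels <- function(trueLabels, predictedLabels, classOrder = NULL,
                           transpose = FALSE) {
  if (length(trueLabels) != length(predictedLabels)) {
    .stopf(
      "label vectors differ in length (%d vs %d)",
      length(trueLabels), length(predictedLabels)
    )
  }
  if (is.null(classOrder)) {
    classOrder <- unique(c(
      if (is.factor(trueLabels)) levels(trueLabels) else unique(as.character(trueLabels)),
      if (is.factor(predictedLabels)) levels(predictedLabels) else unique(as.character(predictedLabels))
    ))
  }
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  outside <- setdiff(unique(c(trueLabels, predictedLabels)), classOrder)
  if (length(outside)) {
    .stopf(
      "label(s) outside the class order: %s",
      paste(outside, collapse = ", ")
    )
  }
  predF <- factor(predictedLabels, levels = classOrder)
  trueF <- factor(trueLabels, levels = classOrder)
  cm <- table(predicted = predF, true = trueF)
  cm <- matrix(as.integer(cm), nrow = length(classOrder),
    dimnames = list(predicted = classOrder, true = classOrder)
  )
  n <- length(trueLabels)
  tp <- diag(cm)
  fp <- rowSums(cm) - tp # predicted c but not c
  fn <- colSums(cm) - tp # truly c but missed
  tn <- n - tp - fp - fn
  perClass <- data.frame(
    class = classOrder,
    TP = as.integer(tp), TN = as.integer(tn),
    FP = as.integer(fp), FN = as.integer(fn),
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NaN),
    recall = ifelse(tp + fn > 0, tp / (tp + fn), NaN),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (transpose) {
    cm <- t(cm)
    names(dimnames(cm)) <- c("true", "predicted")
  }
  new("EvaluationReport",
    confusion = cm,
    accuracy = if (n > 0) 100 * sum(tp) / n else NaN,
    perClass = perClass,
    nTest = as.integer(n)
  )
}

#' @describeIn evaluateLabels confusion matrix accessor
#' @param report an [EvaluationReport-class]
#' @export
confusionMatrix <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  report@confusion
}

#' @describeIn evaluateLabels overall accuracy (percent) accessor
#' @export
accuracy <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  report@accuracy
}

#' @describeIn evaluateLabels per-class TP/TN/FP/FN, precision, recall
#' @export
perClassMetrics <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  report@perClass
}

#' Render an evaluation report as fixed text
#'
#' Deterministic plain-text rendering: the confusion matrix with class
#' headers, the accuracy to two decimal places (e.g. `"66.67"`), and the
#' per-class table. Undefined precision/recall renders as `NaN`.
#'
#' @param report an [EvaluationReport-class]
#' @return character vector of lines
#' @export
reportToText <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  cm <- report@confusion
  classes <- colnames(cm)
  wid <- max(nchar(classes), nchar(as.character(cm)), 4L)
  pad <- function(s) formatC(s, width = wid)
  lines <- c(
    paste0(
      pad("pred\\true"), " ",
      paste(vapply(classes, pad, character(1L)), collapse = " ")
    ),
    vapply(seq_len(nrow(cm)), function(i) {
      paste0(
        pad(rownames(cm)[i]), " ",
        paste(vapply(cm[i, ], pad, character(1L)), collapse = " ")
      )
    }, character(1L)),
    sprintf("accuracy: %.2f", report@accuracy),
    "class TP TN FP FN precision recall",
    vapply(seq_len(nrow(report@perClass)), function(i) {
      pc <- report@perClass[i, ]
      sprintf(
        "%s %d %d %d %d %s %s", pc$class, pc$TP, pc$TN, pc$FP, pc$FN,
        ifelse(is.nan(pc$precision), "NaN", sprintf("%.4f", pc$precision)),
        ifelse(is.nan(pc$recall), "NaN", sprintf("%.4f", pc$recall))
      )
    }, character(1L))
  )
  lines
}

setMethod("show", "EvaluationReport", function(object) {
  cat(reportToText(object), sep = "\n")
})

#' @describeIn classLevels class order of an evaluation report
#' @export
setMethod("classLevels", "EvaluationReport", function(object) {
  colnames(object@confusion)
})
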