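#' Virtual parent of sample-annotated spectral matrices
#'
#' Holds the intensity matrix (samples x variables) plus per-sample IDs and
#' origin labels shared by [SpectralDataset-class] (single instrument block)
#' and [FusedDataset-class] (concatenated blocks).
#'
#' @slot intensities numeric matrix, samples in rows
#' @slot sampleIds unique character IDs, one per row
#' @slot labels factor of origin labels with a fixed level order
#' @keywords internal
#' @export
setClass("AnnotatedSpectra",
  representation("VIRTUAL",
    intensities = "matrix",
    sampleIds = "character",
    labels = "factor"
  )
)

.validAnnotatedSpectra <- function(object) {
  msg <- character()
  x <- object@intensities
  n <- nrow(x)
  if (!is.numeric(x)) {
    msg <- c(msg, "intensities must be a numeric matrix")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    msg <- c(msg, "intensities must be finite with no missing values")
  }
  if (length(object@sampleIds) != n) {
    msg <- c(msg, sprintf(
      "number of sample IDs (%d) != number of rows (%d)",
      length(object@sampleIds), n
    ))
  }
  if (anyDuplicated(object@sampleIds)) {
    dup <- unique(object@sampleIds[duplicated(object@sampleIds)])
    msg <- c(msg, sprintf(
      "duplicate sample ID(s): %s", paste(dup, collapse = ", ")
    ))
  }
  if (length(object@labels) != n) {
    msg <- c(msg, sprintf(
      "number of labels (%d) != number of rows (%d)",
      length(object@labels), n
    ))
  }
  if (anyNA(object@labels)) {
    msg <- c(msg, "labels must not contain NA")
  }
  if (length(msg)) msg else TRUE
}

setValidity("AnnotatedSpectra", .validAnnotatedSpectra)

#' Single-block spectral dataset
#'
#' A sample x variable absorbance matrix together with its instrument axis
#' (wavelength in nm or wavenumber in cm-1), unique sample IDs and a factor of
#' origin labels. The axis is always stored strictly ascending; descending
#' input (common for wavenumber exports) is reversed together with the matrix
#' columns by the constructor and by [loadSpectra()].
#'
#' @slot axis strictly increasing numeric vector, one entry per column
#' @slot units `"nm"` or `"cm-1"`
#' @seealso [SpectralDataset()] for construction, [loadSpectra()],
#'   [saveSpectra()], [generateBlock()]
#' @export
setClass("SpectralDataset",
  contains = "AnnotatedSpectra",
  representation(axis = "numeric", units = "character")
)

setValidity("SpectralDataset", function(object) {
  msg <- character()
  if (length(object@axis) != ncol(object@intensities)) {
    msg <- c(msg, sprintf(
      "axis length (%d) != number of columns (%d)",
      length(object@axis), ncol(object@intensities)
    ))
  }
  if (length(object@axis) >= 2 && any(diff(object@axis) <= 0)) {
    msg <- c(msg, "axis must be strictly increasing")
  }
  if (length(object@units) != 1L || !object@units %in% c("nm", "cm-1")) {
    msg <- c(msg, "units must be \"nm\" or \"cm-1\"")
  }
  if (length(msg)) msg else TRUE
})

#' Low-level fused multi-block dataset
#'
#' Column-wise concatenation of sample-aligned spectral blocks, with
#' block-provenance bookkeeping. `blockSlices` records, for each constituent
#' block in concatenation order, the half-open zero-based column range
#' `[start, end)` it occupies; the slices tile the fused width without gaps or
#' overlaps.
#'
#' @slot blockSlices data.frame with columns `block`, `start`, `end`
#' @seealso [llfuse()], [extractBlock()]
#' @export
setClass("FusedDataset",
  contains = "AnnotatedSpectra",
  representation(blockSlices = "data.frame")
)

setValidity("FusedDataset", function(object) {
  msg <- character()
  sl <- object@blockSlices
  need <- c("block", "start", "end")
  if (!all(need %in% names(sl))) {
    msg <- c(msg, "blockSlices must have columns block, start, end")
  } else {
    if (nrow(sl) == 0L) {
      msg <- c(msg, "at least one block slice required")
    } else {
      if (sl$start[1L] != 0L || sl$end[nrow(sl)] != ncol(object@intensities)) {
        msg <- c(msg, "block slices must span [0, width)")
      }
      if (nrow(sl) > 1L && any(sl$start[-1L] != sl$end[-nrow(sl)])) {
        msg <- c(msg, "block slices must tile without gaps or overlaps")
      }
      if (any(sl$end <= sl$start)) {
        msg <- c(msg, "each block slice must be non-empty")
      }
      if (anyDuplicated(sl$block)) {
        msg <- c(msg, "block names must be unique")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Confusion-matrix evaluation report
#'
#' Confusion matrix with predicted classes in rows and true classes in
#' columns, overall accuracy as a percentage, and per-class TP/TN/FP/FN with
#' precision and recall. Precision or recall with a zero denominator is
#' reported as `NaN`, never silently coerced to 0 or 1.
#'
#' @slot confusion integer matrix; rows = predicted class, columns = true
#'   class, both ordered by the class order fixed at evaluation
#' @slot accuracy overall accuracy in percent, `100 * trace / nTest`
#' @slot perClass data.frame with columns `class`, `TP`, `TN`, `FP`, `FN`,
#'   `precision`, `recall`
#' @slot nTest number of evaluated samples
#' @seealso [evaluateLabels()], [reportToText()]
#' @export
setClass("EvaluationReport",
  representation(
    confusion = "matrix",
    accuracy = "numeric",
    perClass = "data.frame",
    nTest = "integer"
  )
)

setValidity("EvaluationReport", function(object) {
  msg <- character()
  cm <- object@confusion
  if (nrow(cm) != ncol(cm)) {
    msg <- c(msg, "confusion matrix must be square")
  }
  if (sum(cm) != object@nTest) {
    msg <- c(msg, "confusion cells must sum to nTest")
  }
  if (object@nTest > 0L &&
    abs(object@accuracy - 100 * sum(diag(cm)) / object@nTest) > 1e-8) {
    msg <- c(msg, "accuracy must equal 100 * trace / nTest")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted origin classifier
#'
#' Wraps a fitted classifier of one of the four supported families together
#' with the [classifierSpec()] that produced it, the class order captured at
#' fit time, the expected feature count, and the feature mask (if any) that
#' was applied before fitting. [predict()][predict,TrainedSpectralModel-method]
#' applies the same mask and rejects inputs of the wrong width.
#'
#' @slot spec the `ClassifierSpec` list used to fit
#' @slot fit opaque fitted engine state
#' @slot classOrder character vector of class levels at fit time
#' @slot featureCount number of columns the model consumes (after masking)
#' @slot mask logical feature mask over the pre-masking width, or `logical(0)`
#'   when the model was fit on all columns
#' @export
setClass("TrainedSpectralModel",
  representation(
    spec = "list",
    fit = "ANY",
    classOrder = "character",
    featureCount = "integer",
    mask = "logical"
  )
)
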