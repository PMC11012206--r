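#' Construct a SpectralDataset
#'
#' Validates and assembles a single-block spectral dataset. A descending axis
#' is accepted and stored ascending with the matrix columns reversed to
#' match. Character labels are converted to a factor whose level order is the
#' order of first appearance, fixing the class order used by downstream
#' confusion matrices.
#'
#' @param intensities numeric matrix, samples in rows
#' @param axis numeric vector of axis positions, strictly monotonic
#' @param units `"nm"` or `"cm-1"`
#' @param sampleIds character vector of unique IDs; defaults to rownames or
#'   `"S1"`, `"S2"`, ...
#' @param labels factor or character vector of origin labels
#' @return a [SpectralDataset-class]
#' @export
#' @examples
#' d <- SpectralDataset(
#'   matrix(rnorm(12), 3, 4), axis = c(200, 210, 220, 230),
#'   units = "nm", labels = c("A", "A", "B")
#' )
#' nSamples(d)
SpectralDataset <- function(intensities, axis, units,
                            sampleIds = NULL, labels) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  axis <- as.numeric(axis)
  if (length(axis) < 2L) {
    .stopf("a spectral grid needs at least 2 points, got %d", length(axis))
  }
  if (length(axis) != ncol(intensities)) {
    .stopf(
      "axis length (%d) != number of columns (%d)",
      length(axis), ncol(intensities)
    )
  }
  d <- diff(axis)
  if (all(d < 0)) { # descending export: reverse axis and columns together
    axis <- rev(axis)
    intensities <- intensities[, rev(seq_along(axis)), drop = FALSE]
  } else if (any(d <= 0)) {
    .stopf("axis must be strictly monotonic")
  }
  if (is.null(sampleIds)) {
    sampleIds <- rownames(intensities)
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nrow(intensities)))
  }
  sampleIds <- as.character(sampleIds)
  if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  rownames(intensities) <- sampleIds
  colnames(intensities) <- format(axis, trim = TRUE, scientific = FALSE)
  new("SpectralDataset",
    intensities = intensities, axis = axis, units = units,
    sampleIds = sampleIds, labels = labels
  )
}

#' @describeIn intensities single- or fused-block matrix
#' @export
setMethod("intensities", "AnnotatedSpectra", function(object) object@intensities)

#' @describeIn sampleIds IDs of an annotated spectra container
#' @export
setMethod("sampleIds", "AnnotatedSpectra", function(object) object@sampleIds)

#' @describeIn sampleLabels labels of an annotated spectra container
#' @export
setMethod("sampleLabels", "AnnotatedSpectra", function(object) object@labels)

#' @describeIn classLevels fixed class order of a container
#' @export
setMethod("classLevels", "AnnotatedSpectra", function(object) levels(object@labels))

#' @describeIn nSamples rows of the intensity matrix
#' @export
setMethod("nSamples", "AnnotatedSpectra", function(object) nrow(object@intensities))

#' @describeIn nVariables columns of the intensity matrix
#' @export
setMethod("nVariables", "AnnotatedSpectra", function(object) ncol(object@intensities))

#' @describeIn spectralAxis axis of a single block
#' @export
setMethod("spectralAxis", "SpectralDataset", function(object) object@axis)

#' @describeIn axisUnits units of a single block
#' @export
setMethod("axisUnits", "SpectralDataset", function(object) object@units)

#' @describeIn blockSlices provenance table of a fused dataset
#' @export
setMethod("blockSlices", "FusedDataset", function(object) object@blockSlices)

setMethod("show", "SpectralDataset", function(object) {
  cat(sprintf(
    "SpectralDataset: %d samples x %d variables [%s..%s %s]\n",
    nSamples(object), nVariables(object),
    format(min(object@axis)), format(max(object@axis)), object@units
  ))
  cat("classes:", paste(sprintf(
    "%s (%d)", levels(object@labels), tabulate(object@labels)
  ), collapse = ", "), "\n")
})

setMethod("show", "FusedDataset", function(object) {
  sl <- object@blockSlices
  cat(sprintf(
    "FusedDataset: %d samples x %d variables, %d block(s)\n",
    nSamples(object), nVariables(object), nrow(sl)
  ))
  for (i in seq_len(nrow(sl))) {
    cat(sprintf("  %s: columns [%d, %d)\n", sl$block[i], sl$start[i], sl$end[i]))
  }
  cat("classes:", paste(sprintf(
    "%s (%d)", levels(object@labels), tabulate(object@labels)
  ), collapse = ", "), "\n")
})

#' Row subsetting of spectral containers
#'
#' `x[i, ]` keeps the selected samples; the axis (or block slices), the class
#' level order and the ID/label alignment are preserved. Column subsetting is
#' intentionally not provided: use a [FeatureMask][gaSelect()] at training
#' time instead so block bookkeeping stays valid.
#'
#' @param x a [SpectralDataset-class] or [FusedDataset-class]
#' @param i row index vector (integer, logical, or sample IDs)
#' @param j must be missing
#' @param ... unused
#' @param drop ignored
#' @return object of the same class
#' @rdname subset-spectra
#' @export
setMethod("[", "SpectralDataset", function(x, i, j, ..., drop = FALSE) {
  if (!missing(j)) .stopf("column subsetting is not supported; use a feature mask")
  if (is.character(i)) i <- match(i, x@sampleIds)
  initialize(x,
    intensities = x@intensities[i, , drop = FALSE],
    sampleIds = x@sampleIds[i],
    labels = x@labels[i]
  )
})

#' @rdname subset-spectra
#' @export
setMethod("[", "FusedDataset", function(x, i, j, ..., drop = FALSE) {
  if (!missing(j)) .stopf("column subsetting is not supported; use a feature mask")
  if (is.character(i)) i <- match(i, x@sampleIds)
  initialize(x,
    intensities = x@intensities[i, , drop = FALSE],
    sampleIds = x@sampleIds[i],
    labels = x@labels[i]
  )
})
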