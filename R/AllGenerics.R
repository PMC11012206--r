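#' @import methods
NULL

#' Intensity matrix of a spectral container
#'
#' @param object a [SpectralDataset-class] or [FusedDataset-class]
#' @return numeric matrix, samples in rows, spectral variables in columns
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' Sample identifiers
#' @param object a spectral container
#' @return character vector of unique sample IDs, one per row
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' Origin labels
#' @param object a spectral container
#' @return factor of class labels, one per sample; level order is fixed at
#'   construction and drives confusion-matrix row/column order downstream
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))

#' Class levels in their fixed order
#' @param object a spectral container or [EvaluationReport-class]
#' @return character vector
#' @export
setGeneric("classLevels", function(object) standardGeneric("classLevels"))

#' Number of samples (rows)
#' @param object a spectral container
#' @return integer
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' Number of spectral variables (columns)
#' @param object a spectral container
#' @return integer
#' @export
setGeneric("nVariables", function(object) standardGeneric("nVariables"))

#' Spectral axis (wavelengths in nm or wavenumbers in cm-1)
#' @param object a [SpectralDataset-class]
#' @return strictly increasing numeric vector, one entry per column
#' @export
setGeneric("spectralAxis", function(object) standardGeneric("spectralAxis"))

#' Axis units
#' @param object a [SpectralDataset-class]
#' @return `"nm"` or `"cm-1"`
#' @export
setGeneric("axisUnits", function(object) standardGeneric("axisUnits"))

#' Block provenance of a fused dataset
#'
#' @param object a [FusedDataset-class]
#' @return data.frame with columns `block`, `start`, `end`: half-open
#'   zero-based column ranges `[start, end)` tiling the fused width
#' @export
setGeneric("blockSlices", function(object) standardGeneric("blockSlices"))

#' Standard normal variate transform
#'
#' Centers and scales each spectrum (row) to mean 0 and unit sample standard
#' deviation, removing additive offsets and multiplicative scatter.
#'
#' @param object a spectral container or plain numeric matrix (rows = spectra)
#' @param ... unused
#' @return object of the same class with transformed intensities
#' @export
setGeneric("snv", function(object, ...) standardGeneric("snv"))

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * reference`,
#' by ordinary least squares over the spectral variables and returns
#' `(x - a) / b`. With the default `reference = NULL` the column-wise mean of
#' `object` itself is used; in a train/test workflow pass the reference
#' computed from the training partition (see [applyPreprocess()]).
#'
#' @param object a spectral container or numeric matrix (rows = spectra)
#' @param reference numeric vector with one entry per spectral variable, or
#'   `NULL` to use the column means of `object`
#' @param ... unused
#' @return object of the same class with corrected intensities
#' @export
setGeneric("msc", function(object, reference = NULL, ...) standardGeneric("msc"))

#' Savitzky-Golay smoothing
#'
#' Sliding-window local least-squares polynomial smoothing (derivative order
#' 0). Each point is replaced by the value at its position of the polynomial
#' of degree `polyorder` fitted over the centered window. Edges are handled by
#' mirror padding (reflection without repeating the edge point), so the output
#' has the same length as the input.
#'
#' @param object a spectral container or numeric matrix (rows = spectra)
#' @param window odd integer window length, `3 <= window <=` number of
#'   variables
#' @param polyorder polynomial degree, `0 <= polyorder < window`
#' @param ... unused
#' @return object of the same class with smoothed intensities
#' @export
setGeneric("sgSmooth", function(object, window = 11L, polyorder = 2L, ...)
  standardGeneric("sgSmooth"))
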