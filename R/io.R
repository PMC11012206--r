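## Delimited-text dialect for sample-aligned spectral matrices:
##   header:  sample_id,label,<axis value 1>,...,<axis value p>
##   rows:    one sample per line, absorbance values in axis order
## Comma-separated, UTF-8. Axis values live in the header, so block alignment
## across files reduces to matching sample_id columns.

#' Read a spectral matrix from delimited text
#'
#' Parses the package's comma-separated dialect (header
#' `sample_id,label,<axis values...>`) into a validated
#' [SpectralDataset-class]. A descending axis, as commonly exported for
#' wavenumber data, is re-sorted ascending together with its columns.
#'
#' @param path file to read
#' @param units axis units, `"nm"` or `"cm-1"`
#' @return a [SpectralDataset-class]
#' @seealso [saveSpectra()]
#' @export
loadSpectra <- function(path, units) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- utils::read.csv(path,
    header = TRUE, check.names = FALSE,
    colClasses = "character", fileEncoding = "UTF-8"
  )
  if (ncol(df) < 4L) {
    .stopf("%s: expected sample_id, label and >= 2 axis columns", path)
  }
  if (!identical(names(df)[1:2], c("sample_id", "label"))) {
    .stopf("%s: header must start with sample_id,label", path)
  }
  if (nrow(df) == 0L) .stopf("%s: no sample rows", path)
  axis <- suppressWarnings(as.numeric(names(df)[-(1:2)]))
  if (anyNA(axis)) .stopf("%s: non-numeric axis value in header", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    .stopf(
      "%s: duplicate sample ID(s): %s", path,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  vals <- suppressWarnings(
    vapply(df[-(1:2)], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    .stopf(
      "%s: non-numeric cell at sample \"%s\", axis %s",
      path, ids[bad[1L]], format(axis[bad[2L]])
    )
  }
  SpectralDataset(vals,
    axis = axis, units = units,
    sampleIds = ids, labels = df[[2L]]
  )
}

#' Write a spectral matrix as delimited text
#'
#' Writes the dialect read by [loadSpectra()]. Values are printed with 12
#' significant digits, so `loadSpectra(saveSpectra(d))` reproduces `d` within
#' 1e-9 per cell with IDs, labels and label order exact.
#'
#' @param dataset a [SpectralDataset-class]
#' @param path file to write
#' @return invisibly, `path`
#' @export
saveSpectra <- function(dataset, path) {
  stopifnot(is(dataset, "SpectralDataset"))
  if (nSamples(dataset) == 0L) .stopf("refusing to write a dataset with 0 samples")
  header <- paste(
    c("sample_id", "label", format(spectralAxis(dataset), trim = TRUE, scientific = FALSE)),
    collapse = ","
  )
  body <- vapply(seq_len(nSamples(dataset)), function(i) {
    paste(
      c(
        sampleIds(dataset)[i], as.character(sampleLabels(dataset)[i]),
        formatC(intensities(dataset)[i, ], format = "g", digits = 12)
      ),
      collapse = ","
    )
  }, character(1L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
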