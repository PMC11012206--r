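#' Low-level data fusion by column-wise concatenation
#'
#' Concatenates sample-aligned spectral blocks end-to-end into one feature
#' matrix. Rows are aligned by sample ID to the first block's order, so the
#' row order of later blocks is irrelevant; labels must agree per ID. No
#' rescaling is applied at fusion time — scale handling is a preprocessing
#' concern (SNV already standardizes every spectrum within each block).
#'
#' @param blocks ordered list of [SpectralDataset-class] objects; names give
#'   the block names recorded in the provenance table (default `block1`, ...,
#'   or `uv`/`mir` when recognizable from units)
#' @param autoscale if `TRUE`, each block's columns are autoscaled (unit
#'   variance) before concatenation; intended for non-SNV workflows
#' @return a [FusedDataset-class]
#' @export
#' @examples
#' pr <- generatePaired(syntheticConfig(seed = 3))
#' fused <- llfuse(list(mir = pr$mir, uv = pr$uv))
#' blockSlices(fused)
llfuse <- function(blocks, autoscale = FALSE) {
  if (!is.list(blocks) || length(blocks) < 1L) {
    .stopf("llfuse needs a non-empty list of spectral blocks")
  }
  for (b in blocks) stopifnot(is(b, "SpectralDataset"))
  nms <- names(blocks)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- paste0("block", seq_along(blocks))
  }
  if (anyDuplicated(nms)) .stopf("block names must be unique")

  ref <- blocks[[1L]]
  refIds <- sampleIds(ref)
  refLabels <- sampleLabels(ref)
  aligned <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    ids <- sampleIds(b)
    missingIds <- setdiff(refIds, ids)
    extraIds <- setdiff(ids, refIds)
    if (length(missingIds) || length(extraIds)) {
      .stopf(
        "block \"%s\": sample ID sets differ (missing: %s; extra: %s)",
        nms[i],
        paste(utils::head(missingIds, 3L), collapse = ", "),
        paste(utils::head(extraIds, 3L), collapse = ", ")
      )
    }
    ord <- match(refIds, ids)
    lab <- sampleLabels(b)[ord]
    bad <- which(as.character(lab) != as.character(refLabels))
    if (length(bad)) {
      .stopf(
        "label disagreement for sample ID \"%s\" in block \"%s\"",
        refIds[bad[1L]], nms[i]
      )
    }
    m <- intensities(b)[ord, , drop = FALSE]
    if (autoscale) {
      s <- apply(m, 2L, stats::sd)
      s[s < .Machine$double.eps] <- 1
      m <- sweep(m, 2L, s, "/")
    }
    aligned[[i]] <- m
  }
  widths <- vapply(aligned, ncol, integer(1L))
  ends <- cumsum(widths)
  slices <- data.frame(
    block = nms,
    start = c(0L, ends[-length(ends)]),
    end = ends,
    stringsAsFactors = FALSE
  )
  new("FusedDataset",
    intensities = do.call(cbind, aligned),
    sampleIds = refIds, labels = refLabels, blockSlices = slices
  )
}

#' Extract one block's columns from a fused dataset
#'
#' Round-trip companion of [llfuse()]: returns exactly the columns the named
#' block contributed, in its original column order and the fused row order.
#'
#' @param fused a [FusedDataset-class]
#' @param block block name as recorded in [blockSlices()]
#' @return numeric matrix
#' @export
extractBlock <- function(fused, block) {
  stopifnot(is(fused, "FusedDataset"))
  sl <- blockSlices(fused)
  i <- match(block, sl$block)
  if (is.na(i)) {
    .stopf(
      "no block \"%s\" (have: %s)", block,
      paste(sl$block, collapse = ", ")
    )
  }
  intensities(fused)[, (sl$start[i] + 1L):sl$end[i], drop = FALSE]
}
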