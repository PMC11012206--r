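## Per-spectrum preprocessing. All three transforms operate row-wise on the
## intensity matrix and never pool information across samples, with one
## exception: the MSC reference spectrum, which in a train/test workflow must
## come from the training partition only (see applyPreprocess).

.snvMatrix <- function(x, ids = NULL) {
  if (ncol(x) < 2L) .stopf("SNV needs spectra with >= 2 variables")
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1L)) # sample sd, divisor p - 1
  zero <- s < .Machine$double.eps * 1e3
  if (any(zero)) {
    who <- if (is.null(ids)) paste("row", which(zero)[1L]) else ids[which(zero)[1L]]
    .stopf("SNV undefined for zero-variance spectrum: %s", who)
  }
  (x - m) / s
}

.mscMatrix <- function(x, reference, ids = NULL) {
  p <- ncol(x)
  if (length(reference) != p) {
    .stopf(
      "MSC reference length (%d) != number of variables (%d)",
      length(reference), p
    )
  }
  rc <- reference - mean(reference)
  ss <- sum(rc^2)
  if (ss < .Machine$double.eps * 1e3) {
    .stopf("MSC reference has (near-)zero variance")
  }
  ## OLS of each spectrum on the reference: b = cov(x, r)/var(r), a = xbar - b*rbar
  b <- as.numeric(x %*% rc) / ss
  a <- rowMeans(x) - b * mean(reference)
  small <- abs(b) < 1e-12
  if (any(small)) {
    who <- if (is.null(ids)) paste("row", which(small)[1L]) else ids[which(small)[1L]]
    .stopf("MSC slope ~ 0 (spectrum uncorrelated with reference): %s", who)
  }
  (x - a) / b
}

## Central Savitzky-Golay smoothing coefficients from the signal package;
## edges handled by applying the same central filter over a mirror-padded
## spectrum (reflection without repeating the edge point), so outputs keep
## the input length and interior points match the textbook filter exactly.
.sgMatrix <- function(x, window, polyorder) {
  p <- ncol(x)
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window < 3L) {
    .stopf("SG window must be an odd integer >= 3, got %d", window)
  }
  if (window > p) .stopf("SG window (%d) exceeds number of variables (%d)", window, p)
  if (polyorder < 0L || polyorder >= window) {
    .stopf("SG polyorder must satisfy 0 <= polyorder < window")
  }
  hw <- (window - 1L) %/% 2L
  cf <- signal::sgolay(p = polyorder, n = window)[hw + 1L, ]
  pad <- cbind(
    x[, (hw + 1L):2L, drop = FALSE], # mirror, edge point not repeated
    x,
    x[, (p - 1L):(p - hw), drop = FALSE]
  )
  out <- matrix(0, nrow(x), p, dimnames = dimnames(x))
  for (j in seq_len(p)) {
    out[, j] <- pad[, j:(j + window - 1L), drop = FALSE] %*% cf
  }
  out
}

#' @describeIn snv matrix method (rows are spectra)
#' @export
setMethod("snv", "matrix", function(object, ...) .snvMatrix(object, rownames(object)))

#' @describeIn snv dataset method; returns the container with transformed
#'   intensities
#' @export
setMethod("snv", "AnnotatedSpectra", function(object, ...) {
  initialize(object, intensities = .snvMatrix(object@intensities, object@sampleIds))
})

#' @describeIn msc matrix method (rows are spectra)
#' @export
setMethod("msc", "matrix", function(object, reference = NULL, ...) {
  if (is.null(reference)) reference <- colMeans(object)
  .mscMatrix(object, reference, rownames(object))
})

#' @describeIn msc dataset method
#' @export
setMethod("msc", "AnnotatedSpectra", function(object, reference = NULL, ...) {
  if (is.null(reference)) reference <- colMeans(object@intensities)
  initialize(object,
    intensities = .mscMatrix(object@intensities, reference, object@sampleIds)
  )
})

#' @describeIn sgSmooth matrix method (rows are spectra)
#' @export
setMethod("sgSmooth", "matrix", function(object, window = 11L, polyorder = 2L, ...) {
  .sgMatrix(object, window, polyorder)
})

#' @describeIn sgSmooth dataset method
#' @export
setMethod("sgSmooth", "AnnotatedSpectra", function(object, window = 11L,
                                                   polyorder = 2L, ...) {
  initialize(object, intensities = .sgMatrix(object@intensities, window, polyorder))
})

#' Preprocessing specification
#'
#' Bundles a preprocessing method and its parameters for use in
#' [applyPreprocess()] and [runPipeline()].
#'
#' @param method one of `"none"`, `"snv"`, `"msc"`, `"sg"`
#' @param sgWindow odd integer window for `method = "sg"` (default 11)
#' @param sgPolyorder polynomial degree for `method = "sg"` (default 2)
#' @param mscReference optional fixed reference spectrum for `method = "msc"`;
#'   when `NULL` the reference is the column mean of the training partition
#' @return a `PreprocessSpec` list
#' @export
preprocessSpec <- function(method = c("none", "snv", "msc", "sg"),
                           sgWindow = 11L, sgPolyorder = 2L,
                           mscReference = NULL) {
  method <- match.arg(method)
  if (method == "sg") {
    sgWindow <- as.integer(sgWindow)
    sgPolyorder <- as.integer(sgPolyorder)
    if (sgWindow < 3L || sgWindow %% 2L == 0L) {
      .stopf("sgWindow must be an odd integer >= 3")
    }
    if (sgPolyorder < 0L || sgPolyorder >= sgWindow) {
      .stopf("sgPolyorder must satisfy 0 <= sgPolyorder < sgWindow")
    }
  }
  structure(
    list(
      method = method, sgWindow = sgWindow, sgPolyorder = sgPolyorder,
      mscReference = mscReference
    ),
    class = "PreprocessSpec"
  )
}

#' Apply a preprocessing spec to train and test partitions without leakage
#'
#' SNV and SG are strictly per-spectrum, so they are applied independently to
#' each partition. MSC needs a reference spectrum; unless one is fixed in the
#' spec, it is the column-wise mean of the *training* intensities and is then
#' frozen for correcting the test partition, so no test-set statistic ever
#' influences the transform.
#'
#' @param spec a [preprocessSpec()]
#' @param train,test spectral containers (test may be `NULL`)
#' @return list with elements `train`, `test` (transformed containers) and
#'   `mscReference` (the frozen reference, or `NULL`)
#' @export
applyPreprocess <- function(spec, train, test = NULL) {
  stopifnot(inherits(spec, "PreprocessSpec"))
  ref <- NULL
  tf <- switch(spec$method,
    none = identity,
    snv = snv,
    sg = function(d) sgSmooth(d, spec$sgWindow, spec$sgPolyorder),
    msc = {
      ref <- if (is.null(spec$mscReference)) {
        colMeans(intensities(train))
      } else {
        spec$mscReference
      }
      function(d) msc(d, reference = ref)
    }
  )
  list(
    train = tf(train),
    test = if (is.null(test)) NULL else tf(test),
    mscReference = ref
  )
}

#' Human-readable preprocessing label
#'
#' Mirrors the conventional table labels of chemometric model comparisons,
#' e.g. `"SNV"` or `"SNV-GA"`.
#'
#' @param spec a [preprocessSpec()]
#' @param ga whether GA wavelength selection followed preprocessing
#' @return character scalar
#' @export
preprocessLabel <- function(spec, ga = FALSE) {
  base <- switch(spec$method,
    none = "None", snv = "SNV", msc = "MSC", sg = "SG"
  )
  if (ga) paste0(base, "-GA") else base
}
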