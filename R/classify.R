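## Train/test splitting and the four classifier families compared in
## spectroscopy-based origin studies: support-vector (RBF), random forest,
## single-hidden-layer feedforward network, gradient-boosted trees. Each
## family has a small validated hyperparameter set; every stochastic element
## is seeded from the spec so a fit is a pure function of (spec, data).

.FAMILY_PARAMS <- list(
  svc = c("cost", "gamma"),
  rf = c("numTrees", "mtry"),
  ann = c("hidden", "maxit", "learningRate", "l2"),
  gbt = c("nrounds", "maxDepth", "eta", "subsample", "colsampleBytree")
)

.FAMILY_DEFAULTS <- list(
  svc = list(cost = 10, gamma = NULL), # gamma NULL -> 1 / (p * mean feature variance)
  rf = list(numTrees = 500L, mtry = NULL), # mtry NULL -> floor(sqrt(p))
  ann = list(hidden = 100L, maxit = 1000L, learningRate = 1e-3, l2 = 0.03),
  gbt = list(
    nrounds = 300L, maxDepth = 6L, eta = 0.1,
    subsample = 0.8, colsampleBytree = 0.3
  )
)

#' Classifier specification
#'
#' Validated bundle of a classifier family, its hyperparameters and a seed.
#' Unknown hyperparameter names are rejected at construction. Defaults:
#' `svc` — radial-basis kernel, cost 10, kernel width
#' `1 / (feature count * mean feature variance)`; `rf` — 500 trees, `sqrt(p)`
#' candidate features per split; `ann` — one hidden layer of 100 rectified
#' units, cross-entropy loss with weight decay 0.03, up to 1000 iterations;
#' `gbt` — 300 rounds, depth 6, learning rate 0.1, stochastic boosting with
#' row subsample 0.8 and per-tree column subsample 0.3 (split
#' diversification, the standard guard against single-coordinate overfitting
#' on wide spectral matrices).
#'
#' @param family `"svc"`, `"rf"`, `"ann"` or `"gbt"`
#' @param ... family-specific hyperparameters (see Details above)
#' @param seed integer seed for all stochastic elements of the fit
#' @return a `ClassifierSpec` list
#' @export
#' @examples
#' classifierSpec("rf", numTrees = 200)
classifierSpec <- function(family = c("svc", "rf", "ann", "gbt"), ...,
                           seed = 1L) {
  family <- match.arg(family)
  extra <- list(...)
  allowed <- .FAMILY_PARAMS[[family]]
  unknown <- setdiff(names(extra), allowed)
  if (length(unknown) || (length(extra) && is.null(names(extra)))) {
    .stopf(
      "unknown hyperparameter(s) for family \"%s\": %s (allowed: %s)",
      family, paste(unknown, collapse = ", "), paste(allowed, collapse = ", ")
    )
  }
  hp <- utils::modifyList(.FAMILY_DEFAULTS[[family]], extra)
  structure(
    list(family = family, hyperparameters = hp, seed = as.integer(seed)),
    class = "ClassifierSpec"
  )
}

#' Train/test split specification
#'
#' @param trainFraction fraction of samples assigned to training, in (0, 1);
#'   the training size is `floor(trainFraction * n)` overall
#' @param stratified stratify by class (default): per-class training counts
#'   are the floors of `trainFraction * classSize`, with the remaining slots
#'   assigned to the classes with the largest fractional parts
#' @param seed integer seed
#' @return a `SplitSpec` list
#' @export
splitSpec <- function(trainFraction = 0.7, stratified = TRUE, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1) {
    .stopf("trainFraction must be in (0, 1)")
  }
  structure(
    list(
      trainFraction = trainFraction, stratified = isTRUE(stratified),
      seed = as.integer(seed)
    ),
    class = "SplitSpec"
  )
}

#' Split a dataset into train and test partitions
#'
#' Disjoint, exhaustive, seed-reproducible partition. With stratification the
#' overall training size is exactly `floor(trainFraction * n)`: per-class
#' floors first, then the remainder goes to the classes with the largest
#' fractional parts (ties broken by class order).
#'
#' @param dataset a [SpectralDataset-class] or [FusedDataset-class]
#' @param spec a [splitSpec()]
#' @return list with elements `train` and `test` (same class as `dataset`)
#'   and `trainIdx` (integer row indices of the training partition)
#' @export
#' @examples
#' d <- generateBlock(syntheticConfig(seed = 2), "uv")
#' sp <- splitTrainTest(d, splitSpec(seed = 5))
#' nSamples(sp$train); nSamples(sp$test)
splitTrainTest <- function(dataset, spec = splitSpec()) {
  stopifnot(is(dataset, "AnnotatedSpectra"), inherits(spec, "SplitSpec"))
  n <- nSamples(dataset)
  labels <- sampleLabels(dataset)
  nTrain <- floor(spec$trainFraction * n)
  if (nTrain < 1L || nTrain >= n) .stopf("split leaves an empty partition")
  if (spec$stratified) {
    tab <- table(labels)
    if (any(tab < 2L)) {
      .stopf(
        "stratified split needs >= 2 samples per class; class \"%s\" has %d",
        names(tab)[which.min(tab)], min(tab)
      )
    }
    exact <- spec$trainFraction * as.numeric(tab)
    base <- floor(exact)
    remainder <- nTrain - sum(base)
    if (remainder > 0L) {
      extra <- order(exact - base, decreasing = TRUE)[seq_len(remainder)]
      base[extra] <- base[extra] + 1L
    }
    trainIdx <- integer(0)
    .withSeed(spec$seed, {
      for (k in seq_along(levels(labels))) {
        idx <- which(labels == levels(labels)[k])
        trainIdx <- c(trainIdx, idx[sample.int(length(idx), base[k])])
      }
    })
  } else {
    trainIdx <- .withSeed(spec$seed, sample.int(n, nTrain))
  }
  trainIdx <- sort(trainIdx)
  list(
    train = dataset[trainIdx, ],
    test = dataset[-trainIdx, ],
    trainIdx = trainIdx
  )
}

.featureMatrix <- function(data) {
  if (is(data, "AnnotatedSpectra")) intensities(data) else as.matrix(data)
}

#' Train a classifier on (optionally masked) spectral features
#'
#' Fits the family named in `spec` on the training intensities, restricted to
#' the columns of `mask` when one is given. All stochastic elements (forest
#' bootstraps, network initialization, boosting subsampling) are seeded from
#' `spec$seed`, so the fit is reproducible.
#'
#' @param spec a [classifierSpec()]
#' @param train a spectral container, or a numeric matrix with `labels` given
#' @param mask optional logical feature mask (length = training width) or a
#'   `FeatureMask` from [gaSelect()]
#' @param labels labels when `train` is a plain matrix
#' @return a [TrainedSpectralModel-class]
#' @export
trainClassifier <- function(spec, train, mask = NULL, labels = NULL) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  x <- .featureMatrix(train)
  if (is.null(labels)) {
    if (!is(train, "AnnotatedSpectra")) {
      .stopf("labels must be supplied when training on a plain matrix")
    }
    labels <- sampleLabels(train)
  }
  if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  if (nlevels(droplevels(labels)) < 2L) {
    .stopf("training data must contain >= 2 classes")
  }
  if (any(!is.finite(x))) .stopf("training features must be finite")
  maskVec <- logical(0)
  if (!is.null(mask)) {
    maskVec <- if (inherits(mask, "FeatureMask")) mask$bits else as.logical(mask)
    if (length(maskVec) != ncol(x)) {
      .stopf(
        "mask length (%d) != feature count (%d)",
        length(maskVec), ncol(x)
      )
    }
    if (!any(maskVec)) .stopf("feature mask must select at least one variable")
    x <- x[, maskVec, drop = FALSE]
  }
  classOrder <- levels(labels)
  yIdx <- as.integer(labels)
  hp <- spec$hyperparameters
  p <- ncol(x)

  fit <- switch(spec$family,
    svc = {
      gamma <- hp$gamma
      if (is.null(gamma)) {
        mv <- mean(apply(x, 2L, stats::var))
        gamma <- if (mv > 0) 1 / (p * mv) else 1 / p
      }
      .withSeed(spec$seed, e1071::svm(
        x = x, y = labels, type = "C-classification",
        kernel = "radial", cost = hp$cost, gamma = gamma, scale = FALSE
      ))
    },
    rf = {
      mtry <- hp$mtry
      if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
      ranger::ranger(
        x = x, y = labels,
        num.trees = as.integer(hp$numTrees), mtry = min(mtry, p),
        seed = spec$seed, num.threads = 1L
      )
    },
    ann = .mlpFit(
      x, yIdx, length(classOrder),
      hidden = as.integer(hp$hidden), maxit = as.integer(hp$maxit),
      learningRate = hp$learningRate, l2 = hp$l2, seed = spec$seed
    ),
    gbt = .withSeed(spec$seed, {
      dtrain <- xgboost::xgb.DMatrix(x, label = yIdx - 1L, nthread = 1L)
      xgboost::xgb.train(
        params = list(
          objective = "multi:softmax", num_class = length(classOrder),
          max_depth = as.integer(hp$maxDepth), eta = hp$eta,
          subsample = hp$subsample, colsample_bytree = hp$colsampleBytree,
          nthread = 1L, seed = spec$seed
        ),
        data = dtrain, nrounds = as.integer(hp$nrounds), verbose = 0
      )
    })
  )
  new("TrainedSpectralModel",
    spec = unclass(spec), fit = fit, classOrder = classOrder,
    featureCount = as.integer(p), mask = maskVec
  )
}

#' Predict origin labels
#'
#' Applies the model's stored feature mask (if any) and returns one label per
#' row, drawn from the class order captured at fit time. Inputs whose width
#' matches neither the masked nor the pre-masking width are rejected.
#'
#' @param object a [TrainedSpectralModel-class]
#' @param newdata spectral container or numeric matrix
#' @param ... unused
#' @return factor of predicted labels with the fit-time class levels
#' @export
setMethod("predict", "TrainedSpectralModel", function(object, newdata, ...) {
  x <- .featureMatrix(newdata)
  if (length(object@mask)) {
    if (ncol(x) == length(object@mask)) {
      x <- x[, object@mask, drop = FALSE]
    } else if (ncol(x) != object@featureCount) {
      .stopf(
        "feature width %d matches neither the full width %d nor the masked width %d",
        ncol(x), length(object@mask), object@featureCount
      )
    }
  } else if (ncol(x) != object@featureCount) {
    .stopf(
      "feature width %d != model feature count %d",
      ncol(x), object@featureCount
    )
  }
  idx <- switch(object@spec$family,
    svc = as.integer(stats::predict(object@fit, x)),
    rf = as.integer(stats::predict(object@fit,
      data = x, num.threads = 1L,
      seed = object@spec$seed # vote ties must not consume session RNG
    )$predictions),
    ann = .mlpPredict(object@fit, x),
    gbt = as.integer(stats::predict(
      object@fit,
      xgboost::xgb.DMatrix(x, nthread = 1L)
    )) + 1L
  )
  factor(object@classOrder[idx], levels = object@classOrder)
})

setMethod("show", "TrainedSpectralModel", function(object) {
  cat(sprintf(
    "TrainedSpectralModel: family \"%s\", %d feature(s)%s, classes: %s\n",
    object@spec$family, object@featureCount,
    if (length(object@mask)) sprintf(" (masked from %d)", length(object@mask)) else "",
    paste(object@classOrder, collapse = ", ")
  ))
})

#' Classification accuracy of a model on labeled data
#'
#' @param model a [TrainedSpectralModel-class]
#' @param data labeled spectral container
#' @return accuracy in percent
#' @export
accuracyOf <- function(model, data) {
  pred <- predict(model, data)
  100 * mean(as.character(pred) == as.character(sampleLabels(data)))
}
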