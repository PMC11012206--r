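## Genetic-algorithm selection of characteristic wavelengths. Chromosomes
## are boolean masks over spectral variables; fitness is stratified
## cross-validated accuracy of a base classifier on the masked columns,
## computed on TRAINING data only, minus a parsimony penalty proportional to
## the fraction of variables selected. Evaluating fitness on held-out data
## would leak the test set into feature selection and inflate test
## accuracies, so it is deliberately impossible here.

#' Feature mask over spectral variables
#'
#' @param bits logical vector with at least one `TRUE`
#' @return a `FeatureMask` list with fields `bits` and `selectedCount`
#' @export
featureMask <- function(bits) {
  bits <- as.logical(bits)
  if (anyNA(bits)) .stopf("mask bits must be TRUE/FALSE")
  if (!any(bits)) .stopf("a feature mask must select at least one variable")
  structure(
    list(bits = bits, selectedCount = sum(bits)),
    class = "FeatureMask"
  )
}

#' Genetic-algorithm configuration
#'
#' All defaults are standard GA wavelength-selection practice and every one
#' is adjustable. The base classifier defaults to a 200-tree random forest —
#' fast and hyperparameter-robust, which matters since it is refit
#' `cvFolds` times per fitness evaluation.
#'
#' @param populationSize number of chromosomes, >= 2
#' @param generations maximum generations, >= 1
#' @param crossoverProb probability a mating pair undergoes uniform crossover
#' @param mutationProbPerBit per-bit flip probability; `NULL` means `1/p`
#' @param tournamentSize tournament size for parent selection
#' @param elitismCount number of best chromosomes copied unchanged each
#'   generation; must be `< populationSize`
#' @param initDensity Bernoulli density of the initial population, in (0, 1]
#' @param parsimonyLambda weight of the parsimony penalty
#'   `lambda * selectedCount / p`; 0 recovers pure-accuracy fitness
#' @param cvFolds stratified cross-validation folds for fitness, >= 2
#' @param baseClassifier a [classifierSpec()] scored inside the fitness
#' @param patience stop after this many generations without best-fitness
#'   improvement
#' @param seed integer seed; fold assignment, classifier seeds and all GA
#'   randomness derive from it
#' @return a `GAConfig` list
#' @export
gaConfig <- function(populationSize = 50L, generations = 100L,
                     crossoverProb = 0.8, mutationProbPerBit = NULL,
                     tournamentSize = 3L, elitismCount = 1L,
                     initDensity = 0.3, parsimonyLambda = 0.01,
                     cvFolds = 5L, baseClassifier = classifierSpec("rf", numTrees = 200L),
                     patience = 20L, seed = 1L) {
  populationSize <- as.integer(populationSize)
  if (populationSize < 2L) .stopf("populationSize must be >= 2")
  if (as.integer(elitismCount) >= populationSize) {
    .stopf("elitismCount must be < populationSize")
  }
  if (initDensity <= 0 || initDensity > 1) .stopf("initDensity must be in (0, 1]")
  if (crossoverProb < 0 || crossoverProb > 1) .stopf("crossoverProb must be in [0, 1]")
  if (!is.null(mutationProbPerBit) &&
    (mutationProbPerBit < 0 || mutationProbPerBit > 1)) {
    .stopf("mutationProbPerBit must be in [0, 1]")
  }
  if (as.integer(cvFolds) < 2L) .stopf("cvFolds must be >= 2")
  stopifnot(inherits(baseClassifier, "ClassifierSpec"))
  structure(
    list(
      populationSize = populationSize,
      generations = as.integer(generations),
      crossoverProb = crossoverProb,
      mutationProbPerBit = mutationProbPerBit,
      tournamentSize = as.integer(tournamentSize),
      elitismCount = as.integer(elitismCount),
      initDensity = initDensity,
      parsimonyLambda = parsimonyLambda,
      cvFolds = as.integer(cvFolds),
      baseClassifier = baseClassifier,
      patience = as.integer(patience),
      seed = as.integer(seed)
    ),
    class = "GAConfig"
  )
}

#' Cross-validated fitness of a feature mask
#'
#' Mean stratified `cvFolds`-fold cross-validated accuracy (as a fraction) of
#' the configured base classifier restricted to the masked columns of the
#' training data, minus `parsimonyLambda * selectedCount / p`. Fold
#' assignment and the classifier seed derive from `config$seed`, so the value
#' is deterministic.
#'
#' @param mask a [featureMask()] or logical vector
#' @param train labeled training container
#' @param config a [gaConfig()]
#' @return fitness value (at most 1, smaller for larger masks)
#' @export
maskFitness <- function(mask, train, config = gaConfig()) {
  if (!inherits(mask, "FeatureMask")) mask <- featureMask(mask)
  stopifnot(inherits(config, "GAConfig"), is(train, "AnnotatedSpectra"))
  x <- intensities(train)
  labels <- sampleLabels(train)
  if (length(mask$bits) != ncol(x)) {
    .stopf(
      "mask length (%d) != number of variables (%d)",
      length(mask$bits), ncol(x)
    )
  }
  folds <- .stratifiedFolds(labels, config$cvFolds, deriveSeed(config$seed, "cv-folds"))
  xm <- x[, mask$bits, drop = FALSE]
  acc <- vapply(seq_len(config$cvFolds), function(f) {
    inFold <- folds == f
    spec <- config$baseClassifier
    spec$seed <- deriveSeed(config$seed, 1000L + f)
    model <- trainClassifier(spec,
      xm[!inFold, , drop = FALSE],
      labels = droplevels(labels[!inFold])
    )
    pred <- predict(model, xm[inFold, , drop = FALSE])
    mean(as.character(pred) == as.character(labels[inFold]))
  }, numeric(1L))
  mean(acc) - config$parsimonyLambda * mask$selectedCount / ncol(x)
}

## Deterministic comparator: higher fitness wins; ties go to the smaller
## mask, then to the lexicographically smaller bit pattern.
.gaBetter <- function(fitA, maskA, fitB, maskB) {
  if (fitA != fitB) {
    return(fitA > fitB)
  }
  ca <- sum(maskA)
  cb <- sum(maskB)
  if (ca != cb) {
    return(ca < cb)
  }
  d <- which(maskA != maskB)
  if (!length(d)) {
    return(FALSE)
  }
  !maskA[d[1L]] # FALSE sorts before TRUE -> lexicographically smaller wins
}

.repairMask <- function(bits) {
  if (!any(bits)) bits[sample.int(length(bits), 1L)] <- TRUE
  bits
}

#' Genetic-algorithm wavelength selection
#'
#' Evolves a population of boolean wavelength masks under tournament
#' selection, uniform crossover, per-bit flip mutation, zero-mask repair and
#' elitism, scored by `fitnessFun` (by default [maskFitness()] on the
#' training data). Stops after `generations` generations or once the best
#' fitness has not improved for `patience` generations. Fully reproducible
#' from `config$seed`; fitness values are cached per mask, so re-evaluating
#' survivors costs nothing.
#'
#' @param train labeled training container (ignored by a custom `fitnessFun`
#'   that does not use it)
#' @param config a [gaConfig()]
#' @param fitnessFun function `(logical bits) -> numeric` overriding the
#'   default cross-validated fitness; must be deterministic
#' @return list with `mask` (the best-ever [featureMask()]) and `history`, a
#'   list with `bestFitness` (per generation, non-decreasing when
#'   `elitismCount >= 1`), `bestMask` (per generation) and
#'   `selectionFrequency` (per variable, over the final population)
#' @export
gaSelect <- function(train, config = gaConfig(), fitnessFun = NULL) {
  stopifnot(inherits(config, "GAConfig"))
  if (is.null(fitnessFun)) {
    stopifnot(is(train, "AnnotatedSpectra"))
    if (nlevels(droplevels(sampleLabels(train))) < 2L) {
      .stopf("GA selection needs labeled data with >= 2 classes")
    }
    p <- nVariables(train)
    fitnessFun <- function(bits) maskFitness(featureMask(bits), train, config)
  } else {
    p <- if (is(train, "AnnotatedSpectra")) nVariables(train) else as.integer(train)
  }
  if (p < 1L) .stopf("need at least one spectral variable")
  mut <- config$mutationProbPerBit
  if (is.null(mut)) mut <- 1 / p

  cache <- new.env(parent = emptyenv())
  evalFitness <- function(bits) {
    key <- paste(as.integer(bits), collapse = "")
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    v <- fitnessFun(bits)
    cache[[key]] <- v
    v
  }

  nPop <- config$populationSize
  result <- .withSeed(deriveSeed(config$seed, "ga-loop"), {
    pop <- lapply(seq_len(nPop), function(i) {
      .repairMask(stats::runif(p) < config$initDensity)
    })
    fits <- vapply(pop, evalFitness, numeric(1L))

    bestOf <- function(pop, fits) {
      bi <- 1L
      for (i in seq_along(pop)[-1L]) {
        if (.gaBetter(fits[i], pop[[i]], fits[bi], pop[[bi]])) bi <- i
      }
      bi
    }

    bi <- bestOf(pop, fits)
    bestBits <- pop[[bi]]
    bestFit <- fits[bi]
    histFit <- bestFit
    histMask <- list(bestBits)
    stale <- 0L

    for (gen in seq_len(config$generations - 1L)) {
      ## elitism: rank the population with the deterministic comparator
      ord <- seq_len(nPop)
      for (i in seq_len(nPop)) { # selection-sort by comparator (small nPop)
        b <- i
        for (k in seq_len(nPop)) {
          if (k > i && .gaBetter(fits[ord[k]], pop[[ord[k]]], fits[ord[b]], pop[[ord[b]]])) b <- k
        }
        tmp <- ord[i]
        ord[i] <- ord[b]
        ord[b] <- tmp
      }
      elites <- lapply(utils::head(ord, config$elitismCount), function(i) pop[[i]])

      tournament <- function() {
        cand <- sample.int(nPop, config$tournamentSize, replace = TRUE)
        w <- cand[1L]
        for (i in cand[-1L]) {
          if (.gaBetter(fits[i], pop[[i]], fits[w], pop[[w]])) w <- i
        }
        pop[[w]]
      }

      offspring <- vector("list", nPop - config$elitismCount)
      i <- 1L
      while (i <= length(offspring)) {
        p1 <- tournament()
        p2 <- tournament()
        if (stats::runif(1L) < config$crossoverProb) {
          swap <- stats::runif(p) < 0.5
          c1 <- ifelse(swap, p2, p1)
          c2 <- ifelse(swap, p1, p2)
        } else {
          c1 <- p1
          c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (i > length(offspring)) break
          flip <- stats::runif(p) < mut
          child <- xor(child, flip)
          offspring[[i]] <- .repairMask(child)
          i <- i + 1L
        }
      }
      pop <- c(elites, offspring)
      fits <- vapply(pop, evalFitness, numeric(1L))

      bi <- bestOf(pop, fits)
      if (.gaBetter(fits[bi], pop[[bi]], bestFit, bestBits)) {
        improved <- fits[bi] > bestFit
        bestBits <- pop[[bi]]
        bestFit <- fits[bi]
        stale <- if (improved) 0L else stale + 1L
      } else {
        stale <- stale + 1L
      }
      histFit <- c(histFit, bestFit)
      histMask <- c(histMask, list(bestBits))
      if (stale >= config$patience) break
    }

    selFreq <- Reduce(`+`, lapply(pop, as.numeric)) / length(pop)
    list(
      mask = featureMask(bestBits),
      history = list(
        bestFitness = histFit,
        bestMask = lapply(histMask, featureMask),
        selectionFrequency = selFreq
      )
    )
  })
  result
}

#' Write a feature mask as two-column text
#'
#' One row per spectral variable: axis value and a 0/1 selected flag.
#'
#' @param mask a [featureMask()]
#' @param axis numeric axis values (same length as the mask)
#' @param path file to write
#' @return invisibly, `path`
#' @export
saveMask <- function(mask, axis, path) {
  stopifnot(inherits(mask, "FeatureMask"), length(axis) == length(mask$bits))
  df <- data.frame(
    axis = format(axis, trim = TRUE, scientific = FALSE),
    selected = as.integer(mask$bits)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
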