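## End-to-end orchestration: generate/load blocks -> per-block preprocessing
## -> one shared stratified split -> GA wavelength selection on training data
## -> low-level fusion -> train the configured classifier families -> evaluate
## on the held-out partition. One global seed derives every stage's sub-seed,
## so a run is a pure function of its configuration.

#' Pipeline configuration
#'
#' @param data either a [syntheticConfig()] (the cohort is generated) or a
#'   named list of file paths per block, e.g.
#'   `list(uv = "uv.csv", mir = "mir.csv")` in the [loadSpectra()] dialect
#' @param preprocess a [preprocessSpec()] applied to every block, or a named
#'   list of specs per block
#' @param split a [splitSpec()]; its seed is derived from `globalSeed` unless
#'   `deriveSubSeeds = FALSE`
#' @param ga a [gaConfig()], or `NULL` for no wavelength selection
#' @param gaPlacement `"post_fusion"` (default: one GA run on the fused
#'   training matrix), `"per_block"` (GA per block before fusion), or
#'   `"off"`
#' @param blockSets list of character vectors naming the block combinations
#'   to model; default `list(c("mir", "uv"))` — the fused arm with MIR first.
#'   Use e.g. `list("uv", "mir", c("mir", "uv"))` for the single-block
#'   versus fused comparison.
#' @param classifiers named list of [classifierSpec()]s, or a character
#'   vector of family names
#' @param outputDir directory for artifacts (created if needed), or `NULL`
#'   for no files
#' @param globalSeed integer master seed
#' @param deriveSubSeeds derive generator/split/GA/classifier seeds from
#'   `globalSeed` (default); set `FALSE` to honor the seeds already present
#'   in the sub-configurations
#' @return a `PipelineConfig` list
#' @export
pipelineConfig <- function(data = syntheticConfig(),
                           preprocess = preprocessSpec("snv"),
                           split = splitSpec(),
                           ga = gaConfig(),
                           gaPlacement = c("post_fusion", "per_block", "off"),
                           blockSets = list(c("mir", "uv")),
                           classifiers = c("svc", "rf", "ann", "gbt"),
                           outputDir = NULL,
                           globalSeed = 1L,
                           deriveSubSeeds = TRUE) {
  gaPlacement <- match.arg(gaPlacement)
  if (is.character(classifiers)) {
    classifiers <- stats::setNames(
      lapply(classifiers, classifierSpec),
      classifiers
    )
  }
  if (length(classifiers) < 1L) .stopf("at least one classifier required")
  if (is.null(names(classifiers)) || any(!nzchar(names(classifiers)))) {
    names(classifiers) <- vapply(classifiers, function(s) s$family, character(1L))
  }
  for (s in classifiers) stopifnot(inherits(s, "ClassifierSpec"))
  if (!is.list(blockSets)) blockSets <- list(blockSets)
  if (length(blockSets) < 1L) .stopf("at least one block set required")
  syn <- inherits(data, "SyntheticConfig")
  if (!syn && (!is.list(data) || is.null(names(data)))) {
    .stopf("data must be a syntheticConfig or a named list of file paths")
  }
  blockNames <- if (syn) c("uv", "mir") else names(data)
  for (bs in blockSets) {
    if (!all(bs %in% blockNames)) {
      .stopf(
        "unknown block(s) in blockSets: %s",
        paste(setdiff(bs, blockNames), collapse = ", ")
      )
    }
  }
  if (inherits(preprocess, "PreprocessSpec")) {
    preprocess <- stats::setNames(
      rep(list(preprocess), length(blockNames)), blockNames
    )
  }
  if (!all(blockNames %in% names(preprocess))) {
    .stopf("preprocess must cover every block")
  }
  structure(
    list(
      data = data, preprocess = preprocess, split = split,
      ga = ga, gaPlacement = gaPlacement, blockSets = blockSets,
      classifiers = classifiers, outputDir = outputDir,
      globalSeed = as.integer(globalSeed),
      deriveSubSeeds = isTRUE(deriveSubSeeds)
    ),
    class = "PipelineConfig"
  )
}

.resolveConfig <- function(config) {
  gs <- config$globalSeed
  if (config$deriveSubSeeds) {
    if (inherits(config$data, "SyntheticConfig")) {
      config$data$seed <- deriveSeed(gs, "generate")
    }
    config$split$seed <- deriveSeed(gs, "split")
    if (!is.null(config$ga)) config$ga$seed <- deriveSeed(gs, "ga")
    for (i in seq_along(config$classifiers)) {
      config$classifiers[[i]]$seed <- deriveSeed(
        gs, paste0("clf-", names(config$classifiers)[i])
      )
    }
  }
  config
}

.loadBlocks <- function(config) {
  if (inherits(config$data, "SyntheticConfig")) {
    return(generatePaired(config$data))
  }
  units <- c(uv = "nm", mir = "cm-1")
  blocks <- lapply(names(config$data), function(nm) {
    u <- if (nm %in% names(units)) units[[nm]] else "nm"
    loadSpectra(config$data[[nm]], units = u)
  })
  stats::setNames(blocks, names(config$data))
}

#' Run the full origin-classification pipeline
#'
#' Executes, per configured block set: per-block preprocessing (training
#' statistics only), the single shared stratified split, GA wavelength
#' selection on the training partition, low-level fusion, training of every
#' configured classifier, and confusion-matrix evaluation on the held-out
#' partition. The test partition never influences preprocessing references,
#' GA fitness or classifier fitting.
#'
#' @param config a [pipelineConfig()]
#' @param verbose emit stage progress via `message()`
#' @return a `RunResult` list with `cells` (one per block set x classifier:
#'   block set, labels, train/test accuracy, [EvaluationReport-class], the
#'   selected [featureMask()] if any) and `config` (the fully resolved
#'   configuration echo)
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  config <- .resolveConfig(config)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stopf("[stage %s] %s", name, conditionMessage(e))
    })
  }

  t0 <- proc.time()[["elapsed"]]
  blocks <- stage("load", .loadBlocks(config))
  say("loaded %d block(s): %s", length(blocks), paste(names(blocks), collapse = ", "))

  ## one shared split over sample IDs, reused by every cell
  first <- blocks[[1L]]
  ids <- sampleIds(first)
  for (b in blocks[-1L]) {
    if (!identical(sampleIds(b), ids)) {
      .stopf("[stage split] blocks disagree on sample IDs")
    }
  }
  sp <- stage("split", splitTrainTest(first, config$split))
  trainIdx <- sp$trainIdx
  say(
    "split: %d train / %d test", length(trainIdx),
    nSamples(first) - length(trainIdx)
  )

  cells <- list()
  for (bs in config$blockSets) {
    setName <- paste(bs, collapse = "+")
    say("block set %s", setName)

    prep <- stage("preprocess", {
      lapply(stats::setNames(bs, bs), function(nm) {
        applyPreprocess(
          config$preprocess[[nm]],
          train = blocks[[nm]][trainIdx, ],
          test = blocks[[nm]][-trainIdx, ]
        )
      })
    })

    gaOn <- !is.null(config$ga) && config$gaPlacement != "off"
    maskObj <- NULL
    gaHistory <- NULL

    if (length(bs) > 1L) {
      fuseSet <- function(which) {
        llfuse(lapply(stats::setNames(bs, bs), function(nm) prep[[nm]][[which]]))
      }
      if (gaOn && config$gaPlacement == "per_block") {
        sel <- stage("ga", lapply(stats::setNames(bs, bs), function(nm) {
          cfg <- config$ga
          cfg$seed <- deriveSeed(cfg$seed, paste0("block-", nm))
          gaSelect(prep[[nm]]$train, cfg)
        }))
        maskObj <- featureMask(unlist(lapply(bs, function(nm) sel[[nm]]$mask$bits)))
        gaHistory <- lapply(sel, `[[`, "history")
      }
      trainData <- stage("fuse", fuseSet("train"))
      testData <- stage("fuse", fuseSet("test"))
      if (gaOn && config$gaPlacement == "post_fusion") {
        sel <- stage("ga", gaSelect(trainData, config$ga))
        maskObj <- sel$mask
        gaHistory <- sel$history
      }
    } else {
      trainData <- prep[[bs]]$train
      testData <- prep[[bs]]$test
      if (gaOn) {
        sel <- stage("ga", gaSelect(trainData, config$ga))
        maskObj <- sel$mask
        gaHistory <- sel$history
      }
    }
    if (gaOn && !is.null(maskObj)) {
      say("  GA selected %d / %d variables", maskObj$selectedCount, nVariables(trainData))
    }

    for (ci in seq_along(config$classifiers)) {
      clfName <- names(config$classifiers)[ci]
      model <- stage(
        paste0("train-", clfName),
        trainClassifier(config$classifiers[[ci]], trainData, mask = maskObj)
      )
      trainAcc <- accuracyOf(model, trainData)
      pred <- stage(paste0("predict-", clfName), predict(model, testData))
      report <- stage(
        paste0("evaluate-", clfName),
        evaluateLabels(
          sampleLabels(testData), pred,
          classOrder = classLevels(testData)
        )
      )
      say(
        "  %s: train %.2f%% / test %.2f%%", clfName, trainAcc,
        accuracy(report)
      )
      cells[[length(cells) + 1L]] <- list(
        blockSet = setName,
        preprocessing = preprocessLabel(
          config$preprocess[[bs[1L]]],
          ga = gaOn
        ),
        classifier = clfName,
        trainAccuracy = trainAcc,
        testAccuracy = accuracy(report),
        report = report,
        mask = maskObj,
        gaHistory = gaHistory
      )
    }
  }
  say("done in %.1f s", proc.time()[["elapsed"]] - t0)

  result <- structure(
    list(cells = cells, config = config, trainIdx = trainIdx),
    class = "RunResult"
  )
  if (!is.null(config$outputDir)) writeRunResult(result, config$outputDir)
  result
}

#' Comparison table over the cells of a run
#'
#' One row per classifier x preprocessing label, with train/test accuracy
#' columns (2-decimal percentages) per block set — the standard layout of
#' chemometric model-comparison tables.
#'
#' @param result a `RunResult` from [runPipeline()]
#' @return data.frame
#' @export
compareTable <- function(result) {
  stopifnot(inherits(result, "RunResult"), length(result$cells) >= 1L)
  rows <- unique(lapply(result$cells, function(c) {
    list(classifier = c$classifier, preprocessing = c$preprocessing)
  }))
  sets <- unique(vapply(result$cells, `[[`, character(1L), "blockSet"))
  out <- data.frame(
    Model = vapply(rows, `[[`, character(1L), "classifier"),
    Preprocessing = vapply(rows, `[[`, character(1L), "preprocessing"),
    stringsAsFactors = FALSE
  )
  for (s in sets) {
    tr <- te <- rep(NA_character_, nrow(out))
    for (c in result$cells) {
      if (c$blockSet != s) next
      i <- which(out$Model == c$classifier & out$Preprocessing == c$preprocessing)
      tr[i] <- sprintf("%.2f", c$trainAccuracy)
      te[i] <- sprintf("%.2f", c$testAccuracy)
    }
    out[[paste0(s, ".Train")]] <- tr
    out[[paste0(s, ".Test")]] <- te
  }
  out
}

## Serializable echo of a resolved configuration (drops closures/objects).
.configEcho <- function(config) {
  syn <- inherits(config$data, "SyntheticConfig")
  list(
    data = if (syn) {
      list(
        type = "synthetic", seed = config$data$seed,
        nClasses = config$data$nClasses,
        classSizes = as.integer(config$data$classSizes),
        uvAxis = as.numeric(config$data$uvAxis),
        mirAxis = as.numeric(config$data$mirAxis),
        scatterSigma = config$data$scatterSigma,
        offsetSigma = config$data$offsetSigma,
        slopeSigma = config$data$slopeSigma,
        ampJitterSigma = config$data$ampJitterSigma,
        noiseSigma = config$data$noiseSigma
      )
    } else {
      c(list(type = "files"), config$data)
    },
    preprocess = lapply(config$preprocess, function(s) {
      list(method = s$method, sgWindow = s$sgWindow, sgPolyorder = s$sgPolyorder)
    }),
    split = list(
      trainFraction = config$split$trainFraction,
      stratified = config$split$stratified, seed = config$split$seed
    ),
    ga = if (is.null(config$ga)) {
      NULL
    } else {
      list(
        populationSize = config$ga$populationSize,
        generations = config$ga$generations,
        crossoverProb = config$ga$crossoverProb,
        tournamentSize = config$ga$tournamentSize,
        elitismCount = config$ga$elitismCount,
        initDensity = config$ga$initDensity,
        parsimonyLambda = config$ga$parsimonyLambda,
        cvFolds = config$ga$cvFolds,
        patience = config$ga$patience,
        baseClassifier = config$ga$baseClassifier$family,
        seed = config$ga$seed
      )
    },
    gaPlacement = config$gaPlacement,
    blockSets = lapply(config$blockSets, as.character),
    classifiers = lapply(config$classifiers, function(s) {
      c(list(family = s$family, seed = s$seed),
        Filter(Negate(is.null), s$hyperparameters))
    }),
    globalSeed = config$globalSeed
  )
}

#' Write run artifacts as deterministic text files
#'
#' Emits `resolved_config.yaml` (full provenance echo), `comparison.csv`,
#' and per cell a confusion matrix CSV plus (when GA ran) the selected mask.
#' File contents are byte-reproducible for identical configuration and seed.
#'
#' @param result a `RunResult`
#' @param dir output directory, created if needed
#' @return invisibly, the directory
#' @export
writeRunResult <- function(result, dir) {
  stopifnot(inherits(result, "RunResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(.configEcho(result$config), file.path(dir, "resolved_config.yaml"))
  utils::write.csv(compareTable(result), file.path(dir, "comparison.csv"),
    row.names = FALSE, quote = FALSE
  )
  for (c in result$cells) {
    tag <- paste0(gsub("\\+", "_", c$blockSet), "_", c$classifier)
    utils::write.csv(
      as.data.frame.matrix(confusionMatrix(c$report)),
      file.path(dir, paste0("confusion_", tag, ".csv")),
      quote = FALSE
    )
    writeLines(
      reportToText(c$report),
      file.path(dir, paste0("report_", tag, ".txt"))
    )
  }
  ## one mask per block set (shared across that set's classifiers)
  seen <- character(0)
  for (c in result$cells) {
    if (is.null(c$mask) || c$blockSet %in% seen) next
    seen <- c(seen, c$blockSet)
    utils::write.csv(
      data.frame(index = seq_along(c$mask$bits), selected = as.integer(c$mask$bits)),
      file.path(dir, paste0("mask_", gsub("\\+", "_", c$blockSet), ".csv")),
      row.names = FALSE, quote = FALSE
    )
  }
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' Structured-file mirror of [pipelineConfig()]. Recognized top-level keys:
#' `data` (`type: synthetic` with optional generator fields, or `type: files`
#' with per-block paths), `preprocess` (method name or per-block map with
#' optional `sgWindow`/`sgPolyorder`), `split` (`trainFraction`,
#' `stratified`), `ga` (`false` to disable, or [gaConfig()] fields),
#' `gaPlacement`, `blockSets`, `classifiers` (list of family names),
#' `outputDir`, `globalSeed`.
#'
#' @param path YAML file
#' @return a `PipelineConfig`
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$data)) {
    if (identical(y$data$type, "files")) {
      args$data <- y$data[setdiff(names(y$data), "type")]
    } else {
      dataArgs <- y$data[setdiff(names(y$data), "type")]
      args$data <- do.call(syntheticConfig, dataArgs)
    }
  }
  if (!is.null(y$preprocess)) {
    mk <- function(v) {
      if (is.character(v)) preprocessSpec(v) else do.call(preprocessSpec, v)
    }
    args$preprocess <- if (is.character(y$preprocess) || !is.null(y$preprocess$method)) {
      mk(y$preprocess)
    } else {
      lapply(y$preprocess, mk)
    }
  }
  if (!is.null(y$split)) args$split <- do.call(splitSpec, y$split)
  if (!is.null(y$ga)) {
    args$ga <- if (isFALSE(y$ga)) NULL else do.call(gaConfig, y$ga)
    if (isFALSE(y$ga)) args["ga"] <- list(NULL)
  }
  if (!is.null(y$gaPlacement)) args$gaPlacement <- y$gaPlacement
  if (!is.null(y$blockSets)) args$blockSets <- y$blockSets
  if (!is.null(y$classifiers)) args$classifiers <- unlist(y$classifiers)
  if (!is.null(y$outputDir)) args$outputDir <- y$outputDir
  if (!is.null(y$globalSeed)) args$globalSeed <- y$globalSeed
  do.call(pipelineConfig, args)
}
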