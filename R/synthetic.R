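## Seeded two-block spectra simulator.
##
## Generative model per sample i of class c, on axis t (rescaled to [0,1] as
## t~ for the baseline term):
##
##   x_ij = a_i + c_i * t~_j
##        + b_i * sum_k (A_k + delta_{k,c} + eta_{i,k}) * exp(-(t_j - mu_k)^2 / (2 w_k^2))
##        + eps_ij
##
##   b_i   = exp(N(0, scatterSigma^2))   multiplicative scatter gain (log-normal,
##                                       so gains are positive)
##   a_i   ~ N(0, offsetSigma^2)         additive baseline offset
##   c_i   ~ N(0, slopeSigma^2)          linear baseline slope over [0,1]
##   eta   ~ N(0, ampJitterSigma^2)      within-class per-sample peak jitter
##   eps   ~ N(0, noiseSigma^2)          iid measurement noise per point
##
## This is the minimal model under which SNV/MSC are exactly the right
## corrections: an affine distortion (a + b * signal) plus white noise.

#' Gaussian absorption peak specification
#'
#' One peak of the simulator's spectral backbone. A peak is *informative*
#' when its per-class amplitude offsets are not all equal, i.e. its height
#' carries origin information.
#'
#' @param center axis position of the peak (nm or cm-1)
#' @param width Gaussian sigma in axis units, > 0
#' @param baseAmplitude shared peak height (absorbance), >= 0
#' @param classOffsets numeric vector of per-class amplitude deltas, one per
#'   class; `baseAmplitude + min(classOffsets)` must be >= 0
#' @return a `PeakSpec` list with an `informative` flag
#' @export
#' @examples
#' peakSpec(250, width = 15, baseAmplitude = 0.6,
#'          classOffsets = c(0, 0, 0.15, 0.15, 0.3))
peakSpec <- function(center, width, baseAmplitude, classOffsets) {
  stopifnot(length(center) == 1L, length(width) == 1L, length(baseAmplitude) == 1L)
  if (width <= 0) .stopf("peak width must be > 0")
  if (baseAmplitude < 0) .stopf("baseAmplitude must be >= 0")
  classOffsets <- as.numeric(classOffsets)
  if (baseAmplitude + min(classOffsets) < 0) {
    .stopf("baseAmplitude + min(classOffsets) must be >= 0 (no negative peaks)")
  }
  structure(
    list(
      center = center, width = width, baseAmplitude = baseAmplitude,
      classOffsets = classOffsets,
      informative = length(unique(classOffsets)) > 1L
    ),
    class = "PeakSpec"
  )
}

## Default class effect size (absorbance) separating adjacent amplitude
## groups. Within-class peak jitter is fully correlated across a peak's grid
## points, so separation is effectively per informative peak, not per grid
## point: the effect/jitter ratio (0.30 / 0.01) keeps every class boundary
## many sigma wide, and each block carries TWO informative peaks with
## independent jitter so no classifier has to rely on a single brittle
## coordinate. The fused cohort is then cleanly separable while each single
## block still merges two class pairs by construction.
.DEFAULT_EFFECT <- 0.30

## Split-signal class design over 5 classes: the UV informative peak separates
## {1,2} | {3,4} | {5}, the MIR informative peak separates {1,3} | {2,4} | {5}.
## Each block alone leaves two class pairs indistinguishable; the union gives
## every class a unique (UV, MIR) amplitude signature.
.uvClassPattern <- function(d) d * c(0, 0, 1, 1, 2)
.mirClassPattern <- function(d) d * c(0, 1, 0, 1, 2)

#' Default UV peak library
#'
#' Three Gaussian peaks in the 200-300 nm absorption region; the 250 nm
#' (organosulfur-type absorption) and 280 nm peaks carry the UV share of the
#' class signal.
#'
#' @param nClasses number of classes (class-offset vectors are sized to this)
#' @param effect amplitude step (absorbance) between class groups
#' @return list of [peakSpec()]s
#' @export
defaultUvPeaks <- function(nClasses = 5L, effect = .DEFAULT_EFFECT) {
  zero <- rep(0, nClasses)
  uvOff <- if (nClasses == 5L) .uvClassPattern(effect) else zero
  list(
    peakSpec(215, width = 12, baseAmplitude = 0.9, classOffsets = zero),
    peakSpec(250, width = 15, baseAmplitude = 0.6, classOffsets = uvOff),
    peakSpec(280, width = 18, baseAmplitude = 0.4, classOffsets = uvOff)
  )
}

#' Default mid-infrared peak library
#'
#' Five Gaussian peaks at characteristic mid-IR band positions (C-O region
#' 1000-1500, C-H ~2900, O-H ~3400 cm-1); the 1260 and 3400 cm-1 peaks carry
#' the MIR share of the class signal.
#'
#' @inheritParams defaultUvPeaks
#' @return list of [peakSpec()]s
#' @export
defaultMirPeaks <- function(nClasses = 5L, effect = .DEFAULT_EFFECT) {
  zero <- rep(0, nClasses)
  mirOff <- if (nClasses == 5L) .mirClassPattern(effect) else zero
  list(
    peakSpec(1080, width = 60, baseAmplitude = 0.50, classOffsets = zero),
    peakSpec(1260, width = 50, baseAmplitude = 0.45, classOffsets = mirOff),
    peakSpec(1450, width = 40, baseAmplitude = 0.35, classOffsets = zero),
    peakSpec(2900, width = 70, baseAmplitude = 0.55, classOffsets = zero),
    peakSpec(3400, width = 150, baseAmplitude = 0.80, classOffsets = mirOff)
  )
}

#' Synthetic two-block cohort configuration
#'
#' Full parameterization of the paired UV / mid-IR generator. The defaults
#' emulate the study design the package targets: 5 origin classes of sizes
#' 45/46/48/44/42 (225 samples), a UV grid of 190-700 nm at 1 nm (511
#' points), a MIR grid of 400-4000 cm-1 at 10 cm-1 (361 points), and the
#' split-signal peak layout in which the class-informative peaks are divided
#' between the blocks so that neither block alone separates all classes but
#' their fusion does.
#'
#' @param nClasses number of origin classes
#' @param classSizes integer vector of per-class sample counts
#' @param uvAxis,mirAxis numeric `c(start, stop, step)` grid definitions
#' @param uvPeaks,mirPeaks lists of [peakSpec()]s; class-offset vectors must
#'   have `nClasses` entries
#' @param scatterSigma log-scale sd of the multiplicative gain `b`
#' @param offsetSigma sd of the additive baseline offset `a`
#' @param slopeSigma sd of the linear baseline slope `c` (per unit of the
#'   axis rescaled to `[0, 1]`)
#' @param ampJitterSigma within-class per-sample peak-amplitude sd
#' @param noiseSigma iid per-point measurement-noise sd
#' @param seed integer seed; the generator is fully determined by it
#' @param classNames optional class names (default `"C1"`, ...)
#' @return a validated `SyntheticConfig` list; informative axis windows for
#'   each block (used by GA-recovery diagnostics) are attached as
#'   `$informativeWindows`
#' @seealso [generatePaired()], [zeroEffectConfig()]
#' @export
syntheticConfig <- function(nClasses = 5L,
                            classSizes = c(45L, 46L, 48L, 44L, 42L),
                            uvAxis = c(190, 700, 1),
                            mirAxis = c(400, 4000, 10),
                            uvPeaks = defaultUvPeaks(nClasses),
                            mirPeaks = defaultMirPeaks(nClasses),
                            scatterSigma = 0.10,
                            offsetSigma = 0.03,
                            slopeSigma = 0.03,
                            ampJitterSigma = 0.01,
                            noiseSigma = 0.01,
                            seed = 1L,
                            classNames = paste0("C", seq_len(nClasses))) {
  nClasses <- as.integer(nClasses)
  classSizes <- as.integer(classSizes)
  if (length(classSizes) != nClasses) {
    .stopf(
      "length(classSizes) (%d) != nClasses (%d)",
      length(classSizes), nClasses
    )
  }
  if (any(classSizes < 1L)) .stopf("all class sizes must be >= 1")
  if (length(classNames) != nClasses || anyDuplicated(classNames)) {
    .stopf("classNames must be %d unique names", nClasses)
  }
  for (ax in list(uvAxis, mirAxis)) {
    if (length(ax) != 3L || ax[3] <= 0 || ax[2] <= ax[1]) {
      .stopf("axis must be c(start, stop, step) with stop > start, step > 0")
    }
    if (length(seq(ax[1], ax[2], by = ax[3])) < 2L) {
      .stopf("axis grid must have >= 2 points")
    }
  }
  checkPeaks <- function(peaks, block) {
    for (pk in peaks) {
      if (!inherits(pk, "PeakSpec")) .stopf("%s peaks must be peakSpec objects", block)
      if (length(pk$classOffsets) != nClasses) {
        .stopf(
          "%s peak at %s: classOffsets has %d entries, expected %d",
          block, format(pk$center), length(pk$classOffsets), nClasses
        )
      }
    }
  }
  checkPeaks(uvPeaks, "uv")
  checkPeaks(mirPeaks, "mir")
  for (s in c(scatterSigma, offsetSigma, slopeSigma, ampJitterSigma, noiseSigma)) {
    if (s < 0) .stopf("all sigma parameters must be >= 0")
  }
  cfg <- structure(
    list(
      nClasses = nClasses, classSizes = classSizes,
      uvAxis = uvAxis, mirAxis = mirAxis,
      uvPeaks = uvPeaks, mirPeaks = mirPeaks,
      scatterSigma = scatterSigma, offsetSigma = offsetSigma,
      slopeSigma = slopeSigma, ampJitterSigma = ampJitterSigma,
      noiseSigma = noiseSigma, seed = as.integer(seed),
      classNames = classNames
    ),
    class = "SyntheticConfig"
  )
  cfg$informativeWindows <- .informativeWindows(cfg)
  cfg
}

## Axis windows (center +/- 2 sigma) around each informative peak.
.informativeWindows <- function(config) {
  win <- function(peaks) {
    inf <- Filter(function(pk) pk$informative, peaks)
    if (!length(inf)) {
      return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("lo", "hi"))))
    }
    t(vapply(
      inf,
      function(pk) c(lo = pk$center - 2 * pk$width, hi = pk$center + 2 * pk$width),
      numeric(2)
    ))
  }
  list(uv = win(config$uvPeaks), mir = win(config$mirPeaks))
}

#' No-signal control configuration
#'
#' The default cohort with every class offset zeroed: no spectral variable is
#' informative, so downstream classifiers should perform at chance level
#' (about the majority-class share, 48/225 for the default sizes).
#'
#' @param ... arguments forwarded to [syntheticConfig()]
#' @return a `SyntheticConfig`
#' @export
zeroEffectConfig <- function(...) {
  args <- list(...)
  nClasses <- if (!is.null(args$nClasses)) as.integer(args$nClasses) else 5L
  args$uvPeaks <- if (!is.null(args$uvPeaks)) {
    lapply(args$uvPeaks, .stripOffsets, nClasses = nClasses)
  } else {
    lapply(defaultUvPeaks(nClasses), .stripOffsets, nClasses = nClasses)
  }
  args$mirPeaks <- if (!is.null(args$mirPeaks)) {
    lapply(args$mirPeaks, .stripOffsets, nClasses = nClasses)
  } else {
    lapply(defaultMirPeaks(nClasses), .stripOffsets, nClasses = nClasses)
  }
  args$nClasses <- nClasses
  do.call(syntheticConfig, args)
}

.stripOffsets <- function(pk, nClasses) {
  peakSpec(pk$center, pk$width, pk$baseAmplitude, rep(0, nClasses))
}

.axisGrid <- function(ax) seq(ax[1], ax[2], by = ax[3])

#' Generate one spectral block
#'
#' Simulates the block's sample x variable absorbance matrix under the
#' generative model described in [syntheticConfig()]. The draw order within
#' the block's RNG sub-stream is fixed (gain, offset, slope, peak jitter,
#' then noise), so identical configurations give bit-identical output and
#' scaling `noiseSigma` rescales the very same noise realization.
#'
#' @param config a [syntheticConfig()]
#' @param block `"uv"` or `"mir"`
#' @return a [SpectralDataset-class] with `sum(classSizes)` rows
#' @export
#' @examples
#' d <- generateBlock(syntheticConfig(seed = 7), "uv")
#' dim(intensities(d))
generateBlock <- function(config, block = c("uv", "mir")) {
  stopifnot(inherits(config, "SyntheticConfig"))
  block <- match.arg(block)
  ax <- if (block == "uv") config$uvAxis else config$mirAxis
  peaks <- if (block == "uv") config$uvPeaks else config$mirPeaks
  units <- if (block == "uv") "nm" else "cm-1"
  t <- .axisGrid(ax)
  p <- length(t)
  if (p < 2L) .stopf("grid must have >= 2 points")
  tScaled <- (t - t[1]) / (t[p] - t[1])
  n <- sum(config$classSizes)
  classIdx <- rep(seq_len(config$nClasses), config$classSizes)
  nPeaks <- length(peaks)

  seedBlock <- deriveSeed(config$seed, paste0("block-", block))
  draws <- .withSeed(seedBlock, {
    list(
      b = exp(stats::rnorm(n, 0, config$scatterSigma)),
      a = stats::rnorm(n, 0, config$offsetSigma),
      c = stats::rnorm(n, 0, config$slopeSigma),
      eta = if (nPeaks) {
        matrix(stats::rnorm(n * nPeaks, 0, config$ampJitterSigma), n, nPeaks)
      } else {
        matrix(0, n, 0)
      },
      eps = matrix(stats::rnorm(n * p, 0, config$noiseSigma), n, p)
    )
  })

  ## n x p signal: per-sample amplitude matrix times the peak basis
  signal <- matrix(0, n, p)
  if (nPeaks) {
    basis <- t(vapply(
      peaks,
      function(pk) exp(-(t - pk$center)^2 / (2 * pk$width^2)),
      numeric(p)
    )) # nPeaks x p
    amp <- vapply(
      seq_len(nPeaks),
      function(k) {
        pk <- peaks[[k]]
        pk$baseAmplitude + pk$classOffsets[classIdx] + draws$eta[, k]
      },
      numeric(n)
    ) # n x nPeaks
    signal <- amp %*% basis
  }
  x <- draws$a + outer(draws$c, tScaled) + draws$b * signal + draws$eps

  ids <- sprintf("%s%03d", block, seq_len(n))
  SpectralDataset(x,
    axis = t, units = units, sampleIds = ids,
    labels = factor(config$classNames[classIdx], levels = config$classNames)
  )
}

#' Generate the paired UV and mid-IR blocks
#'
#' Both blocks share identical sample IDs, labels and row order; scatter,
#' baseline, jitter and noise are drawn independently per block (separate
#' instruments). Under the default split-signal configuration each block
#' alone leaves some class pairs indistinguishable while the fused blocks
#' separate all classes — the structure the low-level fusion claim is tested
#' against.
#'
#' @param config a [syntheticConfig()]
#' @return list with elements `uv` and `mir`, both [SpectralDataset-class]
#' @export
generatePaired <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  uv <- generateBlock(config, "uv")
  mir <- generateBlock(config, "mir")
  n <- nSamples(uv)
  ids <- sprintf("G%03d", seq_len(n)) # shared IDs across instruments
  uv@sampleIds <- ids
  rownames(uv@intensities) <- ids
  mir@sampleIds <- ids
  rownames(mir@intensities) <- ids
  list(uv = uv, mir = mir)
}

#' Informative axis windows of a configuration
#'
#' Returns, per block, the axis windows (peak center +/- 2 sigma) around
#' every class-informative peak. GA-recovery diagnostics compare selection
#' frequency inside versus outside these windows.
#'
#' @param config a [syntheticConfig()]
#' @return list with matrices `uv` and `mir` (columns `lo`, `hi`)
#' @export
informativeWindows <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  config$informativeWindows
}
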