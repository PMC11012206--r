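# Shared fixtures: everything is generated in code at test time.

# Small labeled dataset with an obvious two-class separation in column 1.
toySeparable <- function(n_per_class = 6, p = 4, gap = 5, seed = 42) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_class * p, sd = 0.1), 2 * n_per_class, p)
    x[seq_len(n_per_class), 1] <- x[seq_len(n_per_class), 1] + gap
    SpectralDataset(
      x,
      axis = seq(100, by = 10, length.out = p), units = "nm",
      sampleIds = sprintf("T%02d", seq_len(2 * n_per_class)),
      labels = rep(c("A", "B"), each = n_per_class)
    )
  })
}

# Down-scaled two-block cohort: 3 classes, coarse grids, one informative
# peak per block (split-signal layout over 3 classes: UV separates class 3,
# MIR separates class 2).
smallConfig <- function(seed = 1, ...) {
  args <- list(
    nClasses = 3L, classSizes = c(10L, 10L, 10L),
    uvAxis = c(200, 300, 5), mirAxis = c(1000, 2000, 50),
    uvPeaks = list(
      peakSpec(230, width = 12, baseAmplitude = 0.5, classOffsets = c(0, 0, 0.3)),
      peakSpec(270, width = 12, baseAmplitude = 0.4, classOffsets = c(0, 0, 0))
    ),
    mirPeaks = list(
      peakSpec(1300, width = 60, baseAmplitude = 0.5, classOffsets = c(0, 0.3, 0)),
      peakSpec(1700, width = 60, baseAmplitude = 0.4, classOffsets = c(0, 0, 0))
    ),
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots # plain replacement; modifyList would merge peak lists
  do.call(syntheticConfig, args)
}

# Independent Savitzky-Golay oracle: per-point least-squares polynomial fit
# over the mirror-padded window, evaluated at the window center.
sgOracle <- function(x, window, polyorder) {
  hw <- (window - 1L) / 2L
  p <- length(x)
  xp <- c(x[(hw + 1L):2L], x, x[(p - 1L):(p - hw)])
  vapply(seq_len(p), function(j) {
    seg <- xp[j:(j + window - 1L)]
    tt <- -hw:hw
    if (polyorder == 0L) {
      mean(seg)
    } else {
      fit <- stats::lm(seg ~ stats::poly(tt, degree = polyorder, raw = TRUE))
      unname(stats::predict(fit, newdata = data.frame(tt = 0)))
    }
  }, numeric(1L))
}

# Deterministic rugged fitness over p bits for GA-vs-exhaustive checks:
# linear weights plus pairwise interactions drawn once from a fixed seed.
ruggedFitness <- function(p = 8, seed = 7) {
  withr::with_seed(seed, {
    w <- rnorm(p)
    q <- matrix(rnorm(p * p, sd = 0.5), p, p)
    q <- (q + t(q)) / 2
    diag(q) <- 0
  })
  function(bits) {
    b <- as.numeric(bits)
    sum(w * b) + as.numeric(t(b) %*% q %*% b) / 2
  }
}

# Exhaustive optimum over all non-empty masks of p bits.
exhaustiveBest <- function(fitnessFun, p) {
  best <- -Inf
  bestBits <- NULL
  for (code in seq_len(2^p - 1L)) {
    bits <- as.logical(bitwAnd(code, 2^(seq_len(p) - 1L)) > 0L)
    f <- fitnessFun(bits)
    if (f > best) {
      best <- f
      bestBits <- bits
    }
  }
  list(fitness = best, bits = bestBits)
}
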