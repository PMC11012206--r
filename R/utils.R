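## Seed derivation: every stochastic stage draws from a sub-seed computed
## from one upstream seed plus a stage tag, so a single global seed makes the
## whole pipeline reproducible while stages stay independently replayable.
## Results stay below 2^31 - 1 so they are valid R integer seeds.

.SEED_MOD <- 2147483647

#' Derive a stage seed from a parent seed
#'
#' Deterministic integer hash of `(seed, tag)` used to give each stochastic
#' stage (generator, split, GA, each classifier, each CV fold) its own
#' reproducible sub-stream.
#'
#' @param seed integer parent seed
#' @param tag integer or character stage tag
#' @return integer in `[1, 2^31 - 2]`
#' @export
#' @examples
#' deriveSeed(1L, "split")
#' deriveSeed(1L, 2L)
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (is.character(tag)) {
    tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  }
  stopifnot(is.numeric(tag), length(tag) == 1L, is.finite(tag))
  ## 64-bit-safe multiplicative mix done in doubles (exact below 2^53)
  h <- (abs(seed) %% .SEED_MOD) * 48271 + (abs(tag) %% .SEED_MOD) * 16807 + 1
  as.integer(h %% (.SEED_MOD - 1) + 1)
}

## Run code under a temporary RNG seed without disturbing the caller's RNG.
.withSeed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Stratified fold assignment: per class, shuffled indices are dealt
## round-robin over folds. Deterministic given the seed.
.stratifiedFolds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    .stopf(
      "class \"%s\" has %d sample(s), fewer than the %d folds",
      names(tab)[which.min(tab)], min(tab), k
    )
  }
  folds <- integer(length(labels))
  .withSeed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
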