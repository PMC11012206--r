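## Minimal single-hidden-layer feedforward network for the ANN classifier
## family: rectified-linear hidden units, softmax output, cross-entropy loss
## with L2 weight decay, full-batch Adam. Written in vectorized base R; on
## feature counts in the hundreds and cohorts in the hundreds of samples a
## fit takes seconds. Inputs are standardized internally with training-set
## statistics (stored and reused at prediction time).

.mlpFit <- function(x, yIdx, nClasses, hidden = 100L, maxit = 1000L,
                    learningRate = 1e-3, l2 = 1e-4, seed = 1L) {
  n <- nrow(x)
  p <- ncol(x)
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale < 1e-12] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")

  y1 <- matrix(0, n, nClasses)
  y1[cbind(seq_len(n), yIdx)] <- 1

  params <- .withSeed(seed, list(
    W1 = matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden), # He init
    b1 = rep(0, hidden),
    W2 = matrix(stats::rnorm(hidden * nClasses, 0, sqrt(2 / hidden)), hidden, nClasses),
    b2 = rep(0, nClasses)
  ))
  W1 <- params$W1
  b1 <- params$b1
  W2 <- params$W2
  b2 <- params$b2

  ## Adam state
  m <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0)
  v <- m
  beta1 <- 0.9
  beta2 <- 0.999
  epsAdam <- 1e-8

  softmaxRows <- function(z) {
    z <- z - apply(z, 1L, max)
    ez <- exp(z)
    ez / rowSums(ez)
  }

  for (it in seq_len(maxit)) {
    h <- xs %*% W1
    h <- sweep(h, 2L, b1, "+")
    hAct <- pmax(h, 0)
    z <- hAct %*% W2
    z <- sweep(z, 2L, b2, "+")
    prob <- softmaxRows(z)

    dz <- (prob - y1) / n
    gW2 <- crossprod(hAct, dz) + l2 * W2
    gb2 <- colSums(dz)
    dh <- dz %*% t(W2)
    dh[h <= 0] <- 0
    gW1 <- crossprod(xs, dh) + l2 * W1
    gb1 <- colSums(dh)

    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (nm in names(grads)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
      mh <- m[[nm]] / (1 - beta1^it)
      vh <- v[[nm]] / (1 - beta2^it)
      step <- learningRate * mh / (sqrt(vh) + epsAdam)
      if (nm == "W1") W1 <- W1 - step
      if (nm == "b1") b1 <- b1 - step
      if (nm == "W2") W2 <- W2 - step
      if (nm == "b2") b2 <- b2 - step
    }
  }
  list(
    W1 = W1, b1 = b1, W2 = W2, b2 = b2,
    center = center, scale = scale, nClasses = nClasses
  )
}

.mlpPredict <- function(fit, x) {
  xs <- sweep(sweep(x, 2L, fit$center), 2L, fit$scale, "/")
  h <- pmax(sweep(xs %*% fit$W1, 2L, fit$b1, "+"), 0)
  z <- sweep(h %*% fit$W2, 2L, fit$b2, "+")
  max.col(z, ties.method = "first")
}
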