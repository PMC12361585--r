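# A compact fully-connected neural network (single hidden layer, ReLU,
# sigmoid output) trained with minibatch Adam on binary cross-entropy with
# L2 weight decay and validation-loss early stopping. This is the shared
# learning engine behind the trainable segmentation backend and the cascade
# classifiers; it is deliberately small enough to train on one CPU in
# seconds while following the classifier training recipe (BCE, Adam,
# lr 1e-3, weight decay 1e-4, batch 32, patience 30).

.dnInit <- function(nIn, nHidden, seed = 1L) {
  .withSeed(seed, {
    list(
      W1 = matrix(stats::rnorm(nIn * nHidden, 0, sqrt(2 / nIn)), nIn, nHidden),
      b1 = rep(0, nHidden),
      W2 = matrix(stats::rnorm(nHidden, 0, sqrt(2 / nHidden)), nHidden, 1),
      b2 = 0)
  })
}

.dnForward <- function(net, X) {
  Z1 <- sweep(X %*% net$W1, 2, net$b1, `+`)
  A1 <- pmax(Z1, 0)
  z2 <- as.vector(A1 %*% net$W2) + net$b2
  p <- 1 / (1 + exp(-z2))
  list(p = p, A1 = A1, Z1 = Z1)
}

.dnPredict <- function(net, X) .dnForward(net, X)$p

.bce <- function(p, y, w = NULL) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  ll <- y * log(p) + (1 - y) * log(1 - p)
  if (is.null(w)) -mean(ll) else -sum(w * ll) / sum(w)
}

# One Adam step over params given gradients; state carries m/v/t.
.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Train on (X, y) with early stopping on (Xval, yval); returns the
# best-validation-loss weights and the per-epoch loss curve.
.dnTrain <- function(X, y, Xval, yval, config = trainConfig(), seed = 1L) {
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L)
    stop("single-class training set: both classes must be present")
  # class-balanced loss weights (the candidate pool is typically
  # dominated by non-lesions)
  w <- rep(1, length(y))
  wVal <- rep(1, length(yval))
  if (config@balanceClasses) {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    w <- ifelse(y == 1, length(y) / (2 * n1), length(y) / (2 * n0))
    wVal <- ifelse(yval == 1, length(y) / (2 * n1), length(y) / (2 * n0))
  }
  net <- .dnInit(ncol(X), config@hidden, seed = seed)
  zero <- lapply(net, function(p) p * 0)
  state <- list(m = zero, v = zero, t = 0)
  best <- list(loss = Inf, net = net, epoch = 0L)
  curve <- data.frame(epoch = integer(), trainLoss = numeric(),
                      valLoss = numeric())
  n <- nrow(X)
  .withSeed(seed + 1L, {
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config@batchSize)
      for (s in starts) {
        idx <- ord[s:min(s + config@batchSize - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        wb <- w[idx]
        fw <- .dnForward(net, Xb)
        dz2 <- wb * (fw$p - yb) / sum(wb)
        gW2 <- crossprod(fw$A1, dz2) + config@weightDecay * net$W2
        gb2 <- sum(dz2)
        dA1 <- tcrossprod(matrix(dz2, ncol = 1), net$W2)
        dZ1 <- dA1 * (fw$Z1 > 0)
        gW1 <- crossprod(Xb, dZ1) + config@weightDecay * net$W1
        gb1 <- colSums(dZ1)
        upd <- .adamStep(net, list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
                         state, config@lr)
        net <- upd$params
        state <- upd$state
      }
      trainLoss <- .bce(.dnPredict(net, X), y, w)
      valLoss <- .bce(.dnPredict(net, Xval), yval, wVal)
      curve <- rbind(curve, data.frame(epoch = epoch, trainLoss = trainLoss,
                                       valLoss = valLoss))
      if (valLoss < best$loss - 1e-9) {
        best <- list(loss = valLoss, net = net, epoch = epoch)
      } else if (epoch - best$epoch >= config@patience) {
        break
      }
    }
  })
  list(net = best$net, curve = curve, bestEpoch = best$epoch)
}
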