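## Minimal neural-network engine used by the 1D-CNN, multi-head attention
## and meta-perceptron learners: dense / conv1d / batch-norm / ReLU /
## max-pool / dropout / single-token multi-head attention layers with
## softmax cross-entropy training under Adam and cosine-annealed learning
## rates.  Matrices are (samples x features); convolutional activations
## are arrays (samples x length x channels).

.nnEps <- 1e-8

## ---- layer constructors -------------------------------------------------

.lyDense <- function(nIn, nOut, bias = TRUE) {
  list(type = "dense",
       params = list(W = matrix(stats::rnorm(nIn * nOut, sd = sqrt(2 / nIn)),
                                nIn, nOut),
                     b = if (bias) rep(0, nOut) else NULL))
}

.lyRelu <- function() list(type = "relu", params = list())

.lyDropout <- function(p) list(type = "dropout", p = p, params = list())

.lyFlatten <- function() list(type = "flatten", params = list())

.lyToChan <- function() list(type = "tochan", params = list())

## batch normalization over features (matrix input) or channels (array
## input is reshaped to (n*L) x C first)
.lyBatchNorm <- function(nFeat, channels = FALSE) {
  list(type = "bn", channels = channels, momentum = 0.9,
       runMean = rep(0, nFeat), runVar = rep(1, nFeat),
       params = list(gamma = rep(1, nFeat), beta = rep(0, nFeat)))
}

.lyConv1d <- function(cIn, cOut, k = 3L, pad = 1L) {
  fanIn <- k * cIn
  list(type = "conv", k = k, cIn = cIn, cOut = cOut, pad = pad,
       params = list(W = matrix(stats::rnorm(fanIn * cOut,
                                             sd = sqrt(2 / fanIn)),
                                fanIn, cOut),
                     b = rep(0, cOut)))
}

.lyMaxPool <- function() list(type = "pool", params = list())

## multi-head attention over a single-token representation: Q, K, V are
## linear maps of the batch-normalized sample vector; with one token per
## sample the softmax attention weight is identically 1 per head, so the
## head outputs equal the value projections and gradients flow through
## W_v and W_o only (dW_q = dW_k = 0 exactly).
.lyMha <- function(dModel, heads) {
  sdq <- sqrt(1 / dModel)
  mk <- function() matrix(stats::rnorm(dModel * dModel, sd = sdq),
                          dModel, dModel)
  list(type = "mha", dModel = dModel, heads = heads, dk = dModel / heads,
       params = list(Wq = mk(), Wk = mk(), Wv = mk(), Wo = mk()))
}

## ---- forward / backward -------------------------------------------------

.lyForward <- function(layer, X, training) {
  p <- layer$params
  switch(layer$type,
    dense = {
      out <- X %*% p$W
      if (!is.null(p$b)) out <- sweep(out, 2L, p$b, `+`)
      list(out = out, cache = list(X = X), layer = layer)
    },
    relu = list(out = pmax(X, 0), cache = list(mask = X > 0), layer = layer),
    dropout = {
      if (training && layer$p > 0) {
        mask <- (stats::runif(length(X)) >= layer$p) / (1 - layer$p)
        dim(mask) <- dim(X)
        list(out = X * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(out = X, cache = list(mask = NULL), layer = layer)
      }
    },
    tochan = {
      list(out = array(X, c(nrow(X), ncol(X), 1L)), cache = NULL,
           layer = layer)
    },
    flatten = {
      d <- dim(X)
      list(out = matrix(X, d[1L], d[2L] * d[3L]), cache = list(dims = d),
           layer = layer)
    },
    bn = {
      d <- dim(X)
      M <- if (length(d) == 3L) matrix(X, d[1L] * d[2L], d[3L]) else X
      if (training) {
        mu <- colMeans(M)
        v <- .colVars(M)
        layer$runMean <- layer$momentum * layer$runMean + (1 - layer$momentum) * mu
        layer$runVar <- layer$momentum * layer$runVar + (1 - layer$momentum) * v
      } else {
        mu <- layer$runMean
        v <- layer$runVar
      }
      invstd <- 1 / sqrt(v + .nnEps)
      xhat <- sweep(sweep(M, 2L, mu), 2L, invstd, `*`)
      out <- sweep(sweep(xhat, 2L, p$gamma, `*`), 2L, p$beta, `+`)
      if (length(d) == 3L) dim(out) <- d
      list(out = out, cache = list(xhat = xhat, invstd = invstd, dims = d,
                                   training = training), layer = layer)
    },
    conv = {
      d <- dim(X)  # n x L x cIn
      n <- d[1L]; L <- d[2L]
      Lout <- L + 2L * layer$pad - layer$k + 1L
      Xp <- array(0, c(n, L + 2L * layer$pad, layer$cIn))
      Xp[, layer$pad + seq_len(L), ] <- X
      cols <- matrix(0, n * Lout, layer$k * layer$cIn)
      for (kk in seq_len(layer$k)) {
        seg <- Xp[, kk:(kk + Lout - 1L), , drop = FALSE]
        cols[, ((kk - 1L) * layer$cIn + 1L):(kk * layer$cIn)] <-
          matrix(seg, n * Lout, layer$cIn)
      }
      outm <- sweep(cols %*% p$W, 2L, p$b, `+`)
      list(out = array(outm, c(n, Lout, layer$cOut)),
           cache = list(cols = cols, n = n, L = L, Lout = Lout),
           layer = layer)
    },
    pool = {
      d <- dim(X)
      Lout <- d[2L] %/% 2L
      x1 <- X[, 2L * seq_len(Lout) - 1L, , drop = FALSE]
      x2 <- X[, 2L * seq_len(Lout), , drop = FALSE]
      mask <- x1 >= x2
      list(out = pmax(x1, x2), cache = list(mask = mask, dims = d),
           layer = layer)
    },
    mha = {
      # one token per sample: softmax(q k^T / sqrt(dk)) over a single key
      # is exactly 1, so per-head output = value projection
      V <- X %*% p$Wv
      list(out = V %*% p$Wo, cache = list(X = X, V = V), layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

.lyBackward <- function(layer, cache, dY) {
  p <- layer$params
  switch(layer$type,
    dense = {
      g <- list(W = crossprod(cache$X, dY))
      if (!is.null(p$b)) g$b <- colSums(dY)
      list(dX = dY %*% t(p$W), grads = g)
    },
    relu = list(dX = dY * cache$mask, grads = list()),
    dropout = {
      dX <- if (is.null(cache$mask)) dY else dY * cache$mask
      list(dX = dX, grads = list())
    },
    tochan = list(dX = matrix(dY, dim(dY)[1L], dim(dY)[2L]), grads = list()),
    flatten = {
      dim(dY) <- cache$dims
      list(dX = dY, grads = list())
    },
    bn = {
      d <- cache$dims
      M <- if (length(d) == 3L) matrix(dY, d[1L] * d[2L], d[3L]) else dY
      xhat <- cache$xhat
      dgamma <- colSums(M * xhat)
      dbeta <- colSums(M)
      if (cache$training) {
        N <- nrow(M)
        t1 <- sweep(M, 2L, dbeta / N)
        t2 <- sweep(xhat, 2L, dgamma / N, `*`)
        dX <- sweep(t1 - t2, 2L, p$gamma * cache$invstd, `*`)
      } else {
        dX <- sweep(M, 2L, p$gamma * cache$invstd, `*`)
      }
      if (length(d) == 3L) dim(dX) <- d
      list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    conv = {
      n <- cache$n; L <- cache$L; Lout <- cache$Lout
      dYm <- matrix(dY, n * Lout, layer$cOut)
      g <- list(W = crossprod(cache$cols, dYm), b = colSums(dYm))
      dcols <- dYm %*% t(p$W)
      dXp <- array(0, c(n, L + 2L * layer$pad, layer$cIn))
      for (kk in seq_len(layer$k)) {
        blk <- dcols[, ((kk - 1L) * layer$cIn + 1L):(kk * layer$cIn),
                     drop = FALSE]
        dXp[, kk:(kk + Lout - 1L), ] <- dXp[, kk:(kk + Lout - 1L), ,
                                            drop = FALSE] +
          array(blk, c(n, Lout, layer$cIn))
      }
      list(dX = dXp[, layer$pad + seq_len(L), , drop = FALSE], grads = g)
    },
    pool = {
      d <- cache$dims
      Lout <- d[2L] %/% 2L
      dX <- array(0, d)
      dX[, 2L * seq_len(Lout) - 1L, ] <- dY * cache$mask
      dX[, 2L * seq_len(Lout), ] <- dY * !cache$mask
      list(dX = dX, grads = list())
    },
    mha = {
      dV <- dY %*% t(p$Wo)
      list(dX = dV %*% t(p$Wv),
           grads = list(Wq = p$Wq * 0, Wk = p$Wk * 0,
                        Wv = crossprod(cache$X, dV),
                        Wo = crossprod(cache$V, dY)))
    },
    stop("unknown layer type: ", layer$type))
}

## forward through the whole net; returns scores plus caches and the
## (possibly updated, for batch-norm running stats) layers
.netForward <- function(net, X, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- .lyForward(net$layers[[i]], X, training)
    X <- r$out
    caches[[i]] <- r$cache
    net$layers[[i]] <- r$layer
  }
  list(scores = X, caches = caches, net = net)
}

.netBackward <- function(net, caches, dY) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    r <- .lyBackward(net$layers[[i]], caches[[i]], dY)
    dY <- r$dX
    grads[[i]] <- r$grads
  }
  grads
}

## ---- Adam optimizer with cosine-annealed learning rate ------------------

.adamInit <- function(net) {
  lapply(net$layers, function(ly)
    lapply(ly$params, function(p) list(m = p * 0, v = p * 0)))
}

.adamStep <- function(net, grads, state, lr, t, weightDecay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]] + weightDecay * net$layers[[i]]$params[[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[i]]$params[[nm]] <-
        net$layers[[i]]$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}

## ---- training loop ------------------------------------------------------

## X: samples x features; y: 0/1 labels.  The learning rate follows the
## cosine annealing schedule from lrMax at epoch 0 to lrMin at the final
## epoch (constant when lrMin == lrMax).
.nnTrain <- function(net, X, y, epochs, batch, lrMax, lrMin = lrMax,
                     weightDecay = 0, seed = 1L) {
  .assert(length(unique(y)) == 2L, "training labels must contain both classes")
  n <- nrow(X)
  Y <- cbind(1 - y, y)  # column 1 = class 0, column 2 = class 1
  withr::with_seed(as.integer(seed), {
    # re-initialize parameters under the training seed for reproducibility
    net$layers <- lapply(net$layers, .reinitLayer)
    state <- .adamInit(net)
    t <- 0L
    for (ep in seq_len(epochs)) {
      lr <- cosineLR(ep - 1L, max(epochs - 1L, 1L), lrMin, lrMax)
      ord <- sample(n)
      for (start in seq(1L, n, by = batch)) {
        ii <- ord[start:min(start + batch - 1L, n)]
        if (length(ii) < 2L) next  # batch-norm needs >= 2 samples
        fw <- .netForward(net, X[ii, , drop = FALSE], training = TRUE)
        net <- fw$net
        P <- .softmaxRows(fw$scores)
        dY <- (P - Y[ii, , drop = FALSE]) / length(ii)
        grads <- .netBackward(net, fw$caches, dY)
        t <- t + 1L
        up <- .adamStep(net, grads, state, lr, t, weightDecay)
        net <- up$net
        state <- up$state
      }
    }
    net
  })
}

.reinitLayer <- function(ly) {
  switch(ly$type,
    dense = {
      nIn <- nrow(ly$params$W); nOut <- ncol(ly$params$W)
      ly$params$W <- matrix(stats::rnorm(nIn * nOut, sd = sqrt(2 / nIn)),
                            nIn, nOut)
      ly
    },
    conv = {
      fanIn <- nrow(ly$params$W); cOut <- ncol(ly$params$W)
      ly$params$W <- matrix(stats::rnorm(fanIn * cOut, sd = sqrt(2 / fanIn)),
                            fanIn, cOut)
      ly
    },
    mha = {
      dm <- ly$dModel
      mk <- function() matrix(stats::rnorm(dm * dm, sd = sqrt(1 / dm)), dm, dm)
      ly$params <- list(Wq = mk(), Wk = mk(), Wv = mk(), Wo = mk())
      ly
    },
    ly)
}

## class-probability forward pass (inference mode; batch-norm uses running
## statistics, dropout is off)
.nnPredict <- function(net, X) {
  .softmaxRows(.netForward(net, X, training = FALSE)$scores)
}
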