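## Stacking ensemble for LRI classification: three base learners
## (polynomial-kernel SVM, 1D-CNN, multi-head attention classifier)
## trained on a 70% "basic" split; their six class scores on the 30%
## "meta" split train a softmax meta-perceptron that emits the final
## interaction probability.

#' Default learner configuration
#'
#' Hyperparameters for the three base learners and the meta-perceptron:
#' SVM with polynomial kernel, `C = 2.5`, `gamma = 0.1`, tolerance 1e-3;
#' 1D-CNN with three conv(3x1, stride 1) + batch-norm + ReLU + max-pool
#' (2x1, stride 2) blocks of 32/64/128 filters and fc(128) -> fc(2),
#' trained 30 epochs at lr 1e-3 (weight decay 1e-5, batch 64); MHA with
#' 8 heads over a 400-dimensional single-token representation
#' (per-head width 50), fc(256, ReLU), 20\% dropout, fc(2); meta
#' perceptron fc(6 -> 12, ReLU) -> fc(12 -> 8, ReLU) -> fc(8 -> 2,
#' softmax) trained with Adam (lr 0.01) under cosine annealing to 1e-6.
#'
#' @param inputDim width of the pair vectors (2d; default 400).
#' @return nested configuration list with elements `svm`, `cnn`, `mha`,
#'   `meta`.
#' @export
defaultLearnerConfig <- function(inputDim = 400L) {
  list(
    svm = list(C = 2.5, gamma = 0.1, kernel = "polynomial", degree = 3L,
               coef0 = 0, tol = 1e-3),
    cnn = list(epochs = 30L, lr = 1e-3, weightDecay = 1e-5, batch = 64L,
               filters = c(32L, 64L, 128L), kernel = 3L, fcHidden = 128L),
    mha = list(inputDim = as.integer(inputDim), heads = 8L, hidden = 256L,
               dropout = 0.2, classes = 2L, epochs = 30L, lr = 1e-3,
               batch = 64L),
    meta = list(widths = c(12L, 8L), classes = 2L, epochs = 100L,
                lr = 0.01, lrMin = 1e-6, batch = 64L)
  )
}

#' Cosine-annealed learning rate
#'
#' `lr(T_cur) = lr_min + (lr_max - lr_min) (1 + cos(pi T_cur / T_max)) / 2`.
#'
#' @param tCur current iteration in `[0, tMax]`.
#' @param tMax maximum iteration (> 0).
#' @param lrMin,lrMax learning-rate bounds, `lrMin <= lrMax`.
#' @return learning rate in `[lrMin, lrMax]`.
#' @examples
#' cosineLR(0, 10, 1e-6, 0.01)   # 0.01
#' cosineLR(10, 10, 1e-6, 0.01)  # 1e-6
#' @export
cosineLR <- function(tCur, tMax, lrMin, lrMax) {
  .assert(tMax > 0 && tCur >= 0 && tCur <= tMax,
          "need 0 <= tCur <= tMax with tMax > 0")
  .assert(lrMin <= lrMax, "lrMin must be <= lrMax")
  lrMin + 0.5 * (lrMax - lrMin) * (1 + cos(pi * tCur / tMax))
}

#' Mean binary cross-entropy loss
#'
#' `-(1/n) sum(p log p_hat + (1 - p) log(1 - p_hat))` with predictions
#' clamped to `[1e-12, 1 - 1e-12]`.
#'
#' @param pHat predicted probabilities of class 1.
#' @param p true 0/1 labels.
#' @return non-negative loss.
#' @export
crossEntropy <- function(pHat, p) {
  .assert(length(pHat) == length(p), "lengths differ")
  q <- pmin(pmax(pHat, 1e-12), 1 - 1e-12)
  -mean(p * log(q) + (1 - p) * log(1 - q))
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V` with the softmax taken over keys per
#' query row.
#'
#' @param Q query matrix (queries x d_k).
#' @param K key matrix (keys x d_k).
#' @param V value matrix (keys x d_v).
#' @return matrix (queries x d_v).
#' @export
scaledDotAttention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  .assert(ncol(Q) == ncol(K), "Q and K widths differ")
  .assert(nrow(K) == nrow(V), "K and V row counts differ")
  W <- .softmaxRows(Q %*% t(K) / sqrt(ncol(K)))
  W %*% V
}

## ---- base learners ------------------------------------------------------

#' Train the polynomial-kernel soft-margin SVM base learner
#'
#' Fits [e1071::svm] with the configured kernel `(gamma x.x' + coef0)^degree`,
#' cost `C` and tolerance, then calibrates class probabilities with a
#' Platt-style logistic fit on the decision values so the learner emits
#' two class scores summing to 1.
#'
#' @param X feature matrix (samples x features).
#' @param y 0/1 labels (both classes required).
#' @param cfg SVM configuration (see [defaultLearnerConfig()]).
#' @return a trained learner (kind `"svm"`) usable with [scoreLearner()].
#' @export
trainSVM <- function(X, y, cfg = defaultLearnerConfig()$svm) {
  .assert(length(unique(y)) == 2L, "SVM training needs both classes")
  fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                    kernel = cfg$kernel, degree = cfg$degree,
                    gamma = cfg$gamma, coef0 = cfg$coef0, cost = cfg$C,
                    tolerance = cfg$tol, scale = FALSE)
  dvm <- attr(stats::predict(fit, X, decision.values = TRUE),
              "decision.values")
  # orient decision values so larger means class 1
  flip <- grepl("^0", colnames(dvm)[1L])
  dv <- if (flip) -dvm[, 1L] else dvm[, 1L]
  platt <- suppressWarnings(
    stats::glm(y ~ dv, family = stats::binomial(),
               data = data.frame(y = y, dv = dv)))
  list(kind = "svm", fit = fit, flip = flip,
       platt = stats::coef(platt), config = cfg)
}

.cnnOutLen <- function(L) L %/% 2L %/% 2L %/% 2L

.makeCnnNet <- function(inputLen, cfg) {
  fl <- cfg$filters
  Lout <- .cnnOutLen(inputLen)
  layers <- list(.lyToChan())
  cIn <- 1L
  for (f in fl) {
    layers <- c(layers, list(.lyConv1d(cIn, f, k = cfg$kernel, pad = 1L),
                             .lyBatchNorm(f, channels = TRUE), .lyRelu(),
                             .lyMaxPool()))
    cIn <- f
  }
  layers <- c(layers, list(.lyFlatten(),
                           .lyDense(fl[length(fl)] * Lout, cfg$fcHidden),
                           .lyRelu(), .lyDense(cfg$fcHidden, 2L)))
  list(layers = layers)
}

#' Train the 1D-CNN base learner
#'
#' The pair vector is treated as a 1-channel signal of length 2d and
#' passed through three conv(3x1, stride 1, zero-padded) -> batch-norm ->
#' ReLU -> max-pool(2x1, stride 2) blocks with 32, 64 and 128 filters,
#' then fc(128, ReLU) -> fc(2).  Trained with Adam on softmax
#' cross-entropy for the configured epochs; initialization and batch
#' order are seeded.
#'
#' @param X feature matrix (samples x features, width >= 8 so the signal
#'   survives three halvings).
#' @param y 0/1 labels.
#' @param cfg CNN configuration (see [defaultLearnerConfig()]).
#' @param seed integer training seed.
#' @return a trained learner (kind `"cnn"`).
#' @export
trainCNN <- function(X, y, cfg = defaultLearnerConfig()$cnn, seed = 1L) {
  .assert(ncol(X) >= 8L,
          "CNN requires feature length >= 8 (three pooling halvings); got %d",
          ncol(X))
  net <- .makeCnnNet(ncol(X), cfg)
  net <- .nnTrain(net, X, y, epochs = cfg$epochs, batch = cfg$batch,
                  lrMax = cfg$lr, weightDecay = cfg$weightDecay, seed = seed)
  list(kind = "cnn", fit = net, config = cfg)
}

.makeMhaNet <- function(cfg) {
  dm <- cfg$inputDim
  list(layers = list(
    .lyBatchNorm(dm),
    .lyMha(dm, cfg$heads),
    .lyDense(dm, cfg$hidden), .lyRelu(),
    .lyDropout(cfg$dropout),
    .lyDense(cfg$hidden, cfg$classes)))
}

#' Train the multi-head attention base learner
#'
#' Each sample is batch-normalized and treated as one token of width
#' `inputDim`; Q, K, V linear maps are split into `heads` heads of width
#' `inputDim / heads` (8 x 50 at the defaults), scaled dot-product
#' attention is applied per head (degenerate for a single token), heads
#' are concatenated and projected, followed by fc(`hidden`, ReLU),
#' dropout and fc(2).
#'
#' @param X feature matrix; width must equal `cfg$inputDim` and be
#'   divisible by `cfg$heads`.
#' @param y 0/1 labels.
#' @param cfg MHA configuration (see [defaultLearnerConfig()]).
#' @param seed integer training seed.
#' @return a trained learner (kind `"mha"`).
#' @export
trainMHA <- function(X, y, cfg = defaultLearnerConfig(ncol(X))$mha,
                     seed = 1L) {
  .assert(ncol(X) == cfg$inputDim,
          "feature width %d does not match inputDim %d", ncol(X), cfg$inputDim)
  .assert(cfg$inputDim %% cfg$heads == 0L,
          "inputDim %d is not divisible by %d heads", cfg$inputDim, cfg$heads)
  net <- .makeMhaNet(cfg)
  net <- .nnTrain(net, X, y, epochs = cfg$epochs, batch = cfg$batch,
                  lrMax = cfg$lr, seed = seed)
  list(kind = "mha", fit = net, config = cfg)
}

#' Class scores from a trained base learner
#'
#' @param learner a learner from [trainSVM()], [trainCNN()] or
#'   [trainMHA()].
#' @param X feature matrix.
#' @return matrix (samples x 2) of class scores `(P(y=0), P(y=1))`
#'   summing to 1 per row.
#' @export
scoreLearner <- function(learner, X) {
  P <- switch(learner$kind,
    svm = {
      dv <- as.numeric(attr(stats::predict(learner$fit, X,
                                           decision.values = TRUE),
                            "decision.values")[, 1L])
      if (learner$flip) dv <- -dv
      eta <- learner$platt[1L] + learner$platt[2L] * dv
      p1 <- 1 / (1 + exp(-eta))
      cbind(1 - p1, p1)
    },
    cnn = .nnPredict(learner$fit, X),
    mha = .nnPredict(learner$fit, X),
    stop("unknown learner kind: ", learner$kind))
  colnames(P) <- c("p0", "p1")
  P
}

#' Six meta-features from the three base learners
#'
#' Columns are the class-0 and class-1 scores of the SVM, CNN and MHA
#' learners in that fixed order:
#' `[SVM(y=0), SVM(y=1), CNN(y=0), CNN(y=1), MHA(y=0), MHA(y=1)]`.
#'
#' @param base list of the three trained learners, ordered svm, cnn, mha.
#' @param X feature matrix.
#' @return matrix (samples x 6).
#' @export
makeMetaFeatures <- function(base, X) {
  .assert(length(base) == 3L &&
            identical(vapply(base, `[[`, character(1), "kind"),
                      c("svm", "cnn", "mha")),
          "base learners must be ordered svm, cnn, mha")
  out <- do.call(cbind, lapply(base, function(b) scoreLearner(b, X)))
  colnames(out) <- c("svm.p0", "svm.p1", "cnn.p0", "cnn.p1",
                     "mha.p0", "mha.p1")
  out
}

.makeMetaNet <- function(cfg) {
  widths <- c(6L, cfg$widths)
  layers <- list()
  for (i in seq_len(length(widths) - 1L)) {
    layers <- c(layers, list(.lyDense(widths[i], widths[i + 1L]), .lyRelu()))
  }
  c_ <- c(layers, list(.lyDense(widths[length(widths)], cfg$classes)))
  list(layers = c_)
}

#' Fit the full stacking ensemble
#'
#' Stratified seeded 70/30 split of the labelled pairs; the SVM, 1D-CNN
#' and MHA base learners are trained on the 70\% basic part, their six
#' class scores on the 30\% meta part train the softmax meta-perceptron
#' (Adam, lr 0.01, cosine annealing to 1e-6, cross-entropy).
#'
#' @param X feature matrix (samples x 2d).
#' @param y 0/1 labels; both classes must be present in both split parts.
#' @param cfg learner configuration (see [defaultLearnerConfig()]).
#' @param seed integer root seed; the split and each learner draw derived
#'   seeds from it.
#' @return a [StackedLRIModel-class].
#' @export
fitStacking <- function(X, y, cfg = defaultLearnerConfig(ncol(X)),
                        seed = 1L) {
  y <- as.integer(y)
  .assert(length(unique(y)) == 2L, "training labels must contain both classes")
  sp <- stratifiedSplit(y, 0.7, childSeed(seed, 0L))
  basic <- sp$first; meta <- sp$second
  for (part in list(basic, meta)) {
    if (length(unique(y[part])) < 2L) {
      stop("a split part is missing a class; re-seed or add samples",
           call. = FALSE)
    }
  }
  Xb <- X[basic, , drop = FALSE]; yb <- y[basic]
  base <- list(trainSVM(Xb, yb, cfg$svm),
               trainCNN(Xb, yb, cfg$cnn, seed = childSeed(seed, 1L)),
               trainMHA(Xb, yb, cfg$mha, seed = childSeed(seed, 2L)))
  E <- makeMetaFeatures(base, X[meta, , drop = FALSE])
  metaNet <- .makeMetaNet(cfg$meta)
  metaNet <- .nnTrain(metaNet, E, y[meta], epochs = cfg$meta$epochs,
                      batch = cfg$meta$batch, lrMax = cfg$meta$lr,
                      lrMin = cfg$meta$lrMin, seed = childSeed(seed, 3L))
  new("StackedLRIModel", base = base, meta = metaNet, config = cfg,
      splitSeed = as.integer(seed), basicIdx = as.integer(basic),
      metaIdx = as.integer(meta))
}

#' Interaction probabilities from a stacked model
#'
#' @param model a [StackedLRIModel-class].
#' @param X feature matrix with the training feature width.
#' @return numeric vector of `P(y = 1)` per pair.
#' @export
predictProba <- function(model, X) {
  E <- makeMetaFeatures(model@base, X)
  .nnPredict(model@meta, E)[, 2L]
}

#' Classify pairs at the 0.5 decision rule
#'
#' A pair is called interacting iff `P(y=1) > P(y=0)`, i.e. strictly
#' greater than 0.5; ties classify as non-interacting.
#'
#' @param model a [StackedLRIModel-class].
#' @param X feature matrix.
#' @return integer vector of 0/1 labels.
#' @export
classifyPairs <- function(model, X) {
  as.integer(predictProba(model, X) > 0.5)
}
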