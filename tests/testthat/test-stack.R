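# Base-learner and ensemble tests run on a small separable two-Gaussian
# task (16 features) so the full suite stays fast; the full-width
# configuration is exercised in test-acceptance.R.

smallTask <- genTwoClassData(n = 200, d = 16, separation = 4, seed = 7)
smallTest <- genTwoClassData(n = 200, d = 16, separation = 4, seed = 8)
smallCfg <- defaultLearnerConfig(16L)

test_that("cosine annealing hits lrMax at 0, lrMin at tMax and the mean halfway", {
  expect_equal(cosineLR(0, 10, 1e-6, 0.01), 0.01)
  expect_equal(cosineLR(10, 10, 1e-6, 0.01), 1e-6)
  expect_equal(cosineLR(5, 10, 0.2, 0.4), 0.3)
  grid <- vapply(seq(0, 17, by = 0.25), cosineLR, numeric(1),
                 tMax = 17, lrMin = 1e-6, lrMax = 0.01)
  expect_true(all(grid >= 1e-6 - 1e-15 & grid <= 0.01 + 1e-15))
  expect_error(cosineLR(5, 4, 0, 1), "tCur")
  expect_error(cosineLR(1, 4, 1, 0), "lrMin")
})

test_that("cross-entropy matches closed forms and hand arithmetic", {
  expect_lt(crossEntropy(c(1, 0, 1), c(1, 0, 1)), 1e-9)
  expect_equal(crossEntropy(rep(0.5, 4), c(1, 0, 1, 0)), log(2))
  expect_equal(crossEntropy(c(0.8, 0.4), c(1, 0)),
               -0.5 * (log(0.8) + log(0.6)))
  expect_gte(crossEntropy(c(0.2), c(1)), 0)
})

test_that("scaled dot-product attention matches degenerate and hand-computed cases", {
  # one key/value row: softmax over a single item returns that value row
  expect_equal(scaledDotAttention(rbind(c(1, 2)), rbind(c(3, 1)),
                                  rbind(c(5, 6))),
               rbind(c(5, 6)))
  # identical keys: uniform weights -> row-mean of V
  V <- rbind(c(1, 0), c(0, 1))
  expect_equal(scaledDotAttention(rbind(c(2, 2)), rbind(c(1, 1), c(1, 1)), V),
               rbind(c(0.5, 0.5)))
  # hand softmax: Q=[1,0], K=I, V=I, weights = softmax(1/sqrt(2), 0)
  w <- exp(c(1 / sqrt(2), 0)); w <- w / sum(w)
  expect_equal(as.numeric(scaledDotAttention(rbind(c(1, 0)), diag(2), diag(2))),
               w)
  expect_error(scaledDotAttention(rbind(1:2), rbind(1:3), rbind(1:3)),
               "widths")
  expect_error(scaledDotAttention(rbind(1:2), rbind(1:2), rbind(1:2, 3:4)),
               "row counts")
})

test_that("the SVM separates well-separated clusters and emits calibrated probabilities", {
  two <- genTwoClassData(n = 200, d = 4, separation = 8, seed = 31)
  fit <- trainSVM(two$X, two$y, defaultLearnerConfig(4L)$svm)
  P <- scoreLearner(fit, two$X)
  expect_equal(rowSums(P), rep(1, 200), tolerance = 1e-9)
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(mean((P[, 2] > 0.5) == two$y), 1)
  # oracle: nearest-centroid classifier agrees on this geometry
  mu0 <- colMeans(two$X[two$y == 0, ]); mu1 <- colMeans(two$X[two$y == 1, ])
  nc <- as.integer(colSums((t(two$X) - mu1)^2) < colSums((t(two$X) - mu0)^2))
  expect_equal(as.integer(P[, 2] > 0.5), nc)
  expect_error(trainSVM(two$X, rep(1, 200)), "both classes")
})

test_that("SVM defaults follow the tuned polynomial-kernel configuration", {
  cfg <- defaultLearnerConfig()$svm
  expect_equal(cfg$C, 2.5)
  expect_equal(cfg$gamma, 0.1)
  expect_equal(cfg$kernel, "polynomial")
  expect_equal(cfg$tol, 1e-3)
})

test_that("the CNN stacks 32/64/128 filters into fc(128) -> fc(2) and learns the task", {
  net <- stackCCC:::.makeCnnNet(16L, smallCfg$cnn)
  convs <- Filter(function(l) l$type == "conv", net$layers)
  expect_equal(vapply(convs, function(l) l$cOut, integer(1)),
               c(32L, 64L, 128L))
  denses <- Filter(function(l) l$type == "dense", net$layers)
  expect_equal(ncol(denses[[1]]$params$W), 128L)
  expect_equal(ncol(denses[[2]]$params$W), 2L)
  expect_equal(nrow(denses[[1]]$params$W), 128L * 2L)  # 128 channels x L/8
  fit <- trainCNN(smallTask$X, smallTask$y, smallCfg$cnn, seed = 1)
  P <- scoreLearner(fit, smallTest$X)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9)
  expect_gte(mean((P[, 2] > 0.5) == smallTest$y), 0.9)
  expect_error(trainCNN(smallTask$X[, 1:4], smallTask$y, smallCfg$cnn),
               ">= 8")
})

test_that("an untrained zero-weight classifier head scores both classes 0.5", {
  net <- list(layers = list(stackCCC:::.lyDense(4L, 2L)))
  net$layers[[1]]$params$W[] <- 0
  P <- stackCCC:::.nnPredict(net, matrix(rnorm(20), 5, 4))
  expect_equal(P, matrix(0.5, 5, 2), ignore_attr = TRUE)
})

test_that("the MHA learner uses per-head width inputDim/heads and learns the task", {
  cfg <- smallCfg$mha
  expect_equal(defaultLearnerConfig(400L)$mha$inputDim / 8, 50)
  expect_equal(cfg$hidden, 256L)
  expect_equal(cfg$dropout, 0.2)
  fit <- trainMHA(smallTask$X, smallTask$y, cfg, seed = 2)
  expect_equal(fit$fit$layers[[2]]$dk, 2)  # 16 / 8 heads
  P <- scoreLearner(fit, smallTest$X)
  expect_gte(mean((P[, 2] > 0.5) == smallTest$y), 0.9)
  badCfg <- cfg; badCfg$inputDim <- 15L
  expect_error(trainMHA(smallTask$X[, 1:15], smallTask$y, badCfg),
               "divisible")
})

test_that("meta-features are the six ordered base-learner class scores", {
  sv <- trainSVM(smallTask$X, smallTask$y, smallCfg$svm)
  cn <- trainCNN(smallTask$X, smallTask$y, smallCfg$cnn, seed = 1)
  mh <- trainMHA(smallTask$X, smallTask$y, smallCfg$mha, seed = 2)
  E <- makeMetaFeatures(list(sv, cn, mh), smallTest$X)
  expect_equal(ncol(E), 6)
  for (blk in list(1:2, 3:4, 5:6)) {
    expect_equal(rowSums(E[, blk]), rep(1, nrow(E)), tolerance = 1e-9)
  }
  # ordering is part of the contract: swapping learners must be rejected
  expect_error(makeMetaFeatures(list(cn, sv, mh), smallTest$X), "ordered")
})

test_that("stacking splits 70/30, is seed-deterministic and beats chance decisively", {
  model <- fitStacking(smallTask$X, smallTask$y, smallCfg, seed = 5)
  n <- nrow(smallTask$X)
  expect_equal(length(model@basicIdx), round(0.7 * n), tolerance = 1)
  expect_equal(sort(c(model@basicIdx, model@metaIdx)), seq_len(n))
  # meta-perceptron widths 6 -> 12 -> 8 -> 2
  widths <- vapply(Filter(function(l) l$type == "dense", model@meta$layers),
                   function(l) dim(l$params$W), integer(2))
  expect_equal(widths, cbind(c(6L, 12L), c(12L, 8L), c(8L, 2L)))
  p <- predictProba(model, smallTest$X)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(rocAuc(smallTest$y, p), 0.95)
  model2 <- fitStacking(smallTask$X, smallTask$y, smallCfg, seed = 5)
  expect_identical(p, predictProba(model2, smallTest$X))
  expect_identical(model@basicIdx, model2@basicIdx)
})

test_that("classification uses the strict P(y=1) > 0.5 rule", {
  model <- fitStacking(smallTask$X, smallTask$y, smallCfg, seed = 5)
  p <- predictProba(model, smallTest$X)
  expect_equal(classifyPairs(model, smallTest$X), as.integer(p > 0.5))
})
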