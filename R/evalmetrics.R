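## Binary-classification metrics and the repeated stratified k-fold
## cross-validation harness.

#' Confusion counts for binary predictions
#'
#' @param yTrue,yPred equal-length 0/1 vectors.
#' @return named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusionCounts <- function(yTrue, yPred) {
  .assert(length(yTrue) == length(yPred), "label vectors differ in length")
  .assert(length(yTrue) >= 1L, "empty input")
  .assert(all(yTrue %in% c(0, 1)) && all(yPred %in% c(0, 1)),
          "labels must be 0/1")
  c(TP = sum(yTrue == 1 & yPred == 1), FP = sum(yTrue == 0 & yPred == 1),
    TN = sum(yTrue == 0 & yPred == 0), FN = sum(yTrue == 1 & yPred == 0))
}

#' Precision, recall, accuracy and F1 from confusion counts
#'
#' Degenerate 0/0 ratios (e.g. precision with no positive predictions)
#' are reported as 0 so reports never contain NaN.
#'
#' @param counts named vector from [confusionCounts()].
#' @return named numeric vector `c(precision, recall, accuracy, f1)`.
#' @export
binaryMetrics <- function(counts) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe(counts[["TP"]], counts[["TP"]] + counts[["FP"]])
  recall <- safe(counts[["TP"]], counts[["TP"]] + counts[["FN"]])
  accuracy <- safe(counts[["TP"]] + counts[["TN"]], sum(counts))
  f1 <- safe(2 * precision * recall, precision + recall)
  c(precision = precision, recall = recall, accuracy = accuracy, f1 = f1)
}

#' Area under the ROC curve
#'
#' The probability that a random positive is scored above a random
#' negative, with ties counted one half (equivalent to trapezoidal ROC
#' integration); computed from the Mann-Whitney rank statistic.
#'
#' @param yTrue 0/1 labels (both classes required).
#' @param scores numeric scores, larger = more positive.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(yTrue, scores) {
  .assert(length(yTrue) == length(scores), "lengths differ")
  nPos <- sum(yTrue == 1)
  nNeg <- sum(yTrue == 0)
  .assert(nPos > 0 && nNeg > 0, "both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[yTrue == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve over decreasing score
#' thresholds (tied scores are processed as one threshold):
#' `sum (R_i - R_{i-1}) P_i`.
#'
#' @inheritParams rocAuc
#' @return AUPR in `[0, 1]`.
#' @export
prAuc <- function(yTrue, scores) {
  .assert(length(yTrue) == length(scores), "lengths differ")
  nPos <- sum(yTrue == 1)
  .assert(nPos > 0 && sum(yTrue == 0) > 0, "both classes required for AUPR")
  ord <- order(scores, decreasing = TRUE)
  y <- yTrue[ord]
  s <- scores[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # keep the last index of each tied-score block
  last <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / nPos
  sum(diff(c(0, recall)) * precision)
}

#' Jaccard index of two identifier sets
#'
#' `|A intersect B| / |A union B|`; 0 when both sets are empty.
#'
#' @param A,B vectors treated as sets.
#' @return similarity in `[0, 1]`.
#' @export
jaccardIndex <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0) return(0)
  length(intersect(A, B)) / u
}

## stratified fold assignment: within each class, shuffled indices are
## dealt round-robin into k folds, so fold sizes differ by at most one
.stratifiedFolds <- function(y, k, seed) {
  .assert(all(table(y) >= k), "each class needs at least k samples")
  withr::with_seed(as.integer(seed), {
    folds <- integer(length(y))
    offset <- 0L
    for (cls in sort(unique(y))) {
      ii <- sample(which(y == cls))
      folds[ii] <- (seq_along(ii) + offset - 1L) %% k + 1L
      offset <- offset + length(ii)  # stagger so fold sizes stay balanced
    }
    folds
  })
}

#' Repeated stratified k-fold cross-validation
#'
#' Per repeat the data are reshuffled (seeded) and split into k
#' stratified folds; each fold is tested exactly once against a model
#' trained on the remaining folds.  Metrics are computed per fold and
#' aggregated as mean and standard deviation over all `k * repeats`
#' folds.
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param trainer function `(X, y) -> model` where
#'   `scorer(model, X) -> P(y=1)`; by default `trainer` must return a
#'   function of the test features that emits `P(y=1)`.
#' @param k number of folds (default 5).
#' @param repeats number of repeats (default 20).
#' @param seed integer root seed.
#' @return list of class `cvReport` with `folds` (one row per evaluated
#'   fold: precision, recall, accuracy, f1, auc, aupr) and `summary`
#'   (mean and sd per metric).
#' @export
repeatedCV <- function(X, y, trainer, k = 5L, repeats = 20L, seed = 1L) {
  y <- as.integer(y)
  .assert(nrow(X) >= k, "need at least k samples")
  rows <- list()
  for (r in seq_len(repeats)) {
    folds <- .stratifiedFolds(y, k, childSeed(seed, r))
    for (f in seq_len(k)) {
      te <- which(folds == f)
      tr <- which(folds != f)
      scorer <- trainer(X[tr, , drop = FALSE], y[tr])
      p1 <- scorer(X[te, , drop = FALSE])
      pred <- as.integer(p1 > 0.5)
      mets <- binaryMetrics(confusionCounts(y[te], pred))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, t(mets),
        auc = rocAuc(y[te], p1), aupr = prAuc(y[te], p1))
    }
  }
  folds <- do.call(rbind, rows)
  metricCols <- c("precision", "recall", "accuracy", "f1", "auc", "aupr")
  summary <- data.frame(
    metric = metricCols,
    mean = vapply(folds[metricCols], mean, numeric(1)),
    sd = vapply(folds[metricCols], stats::sd, numeric(1)),
    row.names = NULL)
  structure(list(folds = folds, summary = summary, k = k, repeats = repeats),
            class = "cvReport")
}

#' @export
print.cvReport <- function(x, ...) {
  cat(sprintf("Repeated stratified CV: %d folds x %d repeats\n", x$k,
              x$repeats))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
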