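## Negative-pair construction in the positive-unlabeled setting: the
## positive pairs form one cluster; unlabeled candidates whose Euclidean
## distance to the positive centroid falls strictly outside a band around
## the positive distance range are taken as negatives.

#' Centroid of a set of positive pair vectors
#'
#' @param positives a [PairFeatureSet-class] or numeric matrix of pair
#'   vectors (rows = pairs).
#' @return numeric vector, the coordinate-wise arithmetic mean.
#' @export
pairCentroid <- function(positives) {
  X <- if (methods::is(positives, "PairFeatureSet")) pairFeatures(positives)
       else as.matrix(positives)
  .assert(nrow(X) >= 1L, "centroid requires at least one positive pair")
  colMeans(X)
}

#' Euclidean distance from a pair vector to the centroid
#'
#' @param b numeric pair vector (or matrix of rows).
#' @param a numeric centroid vector of the same length.
#' @return non-negative distance(s).
#' @examples
#' distanceToCentroid(c(3, 4), c(0, 0))  # 5
#' @export
distanceToCentroid <- function(b, a) {
  if (is.matrix(b)) {
    .assert(ncol(b) == length(a), "vector lengths differ (%d vs %d)",
            ncol(b), length(a))
    sqrt(rowSums(sweep(b, 2L, a)^2))
  } else {
    .assert(length(b) == length(a), "vector lengths differ (%d vs %d)",
            length(b), length(a))
    sqrt(sum((b - a)^2))
  }
}

#' Exclusion-band bounds from positive centroid distances
#'
#' With `minDis`/`maxDis` the smallest/largest positive distance and
#' `disLen = maxDis - minDis`, the band is
#' `minRange = minDis + (1 - pre) * 0.5 * disLen` and
#' `maxRange = maxDis - (1 - pre) * 0.5 * disLen`.  `pre = 1` keeps the
#' full positive range; `pre = 0` collapses the band to its midpoint.
#'
#' @param positiveDistances numeric vector of positive-to-centroid
#'   distances.
#' @param pre band width parameter in `[0, 1]` (default 0.6).
#' @return named list with `minDis`, `maxDis`, `disLen`, `minRange`,
#'   `maxRange`.
#' @examples
#' computeSelectionRange(c(2, 10), pre = 0.6)  # band [3.6, 8.4]
#' @export
computeSelectionRange <- function(positiveDistances, pre = 0.6) {
  .assert(length(positiveDistances) >= 1L, "no positive distances supplied")
  .assert(is.numeric(pre) && length(pre) == 1L && pre >= 0 && pre <= 1,
          "pre must lie in [0, 1]")
  minDis <- min(positiveDistances)
  maxDis <- max(positiveDistances)
  disLen <- maxDis - minDis
  shrink <- (1 - pre) * 0.5 * disLen
  list(minDis = minDis, maxDis = maxDis, disLen = disLen,
       minRange = minDis + shrink, maxRange = maxDis - shrink)
}

#' Build a negative-selection model from positive pairs
#'
#' Computes the positive centroid, the distances of all positives to it,
#' and the exclusion band for a given `pre`.
#'
#' @param positives a [PairFeatureSet-class] or matrix of positive pair
#'   vectors.
#' @param pre band width parameter in `[0, 1]` (default 0.6).
#' @return a [NegativeSelectionModel-class].
#' @export
buildNegativeSelectionModel <- function(positives, pre = 0.6) {
  X <- if (methods::is(positives, "PairFeatureSet")) pairFeatures(positives)
       else as.matrix(positives)
  a <- pairCentroid(X)
  rng <- computeSelectionRange(distanceToCentroid(X, a), pre)
  new("NegativeSelectionModel", centroid = a, minDis = rng$minDis,
      maxDis = rng$maxDis, disLen = rng$disLen, minRange = rng$minRange,
      maxRange = rng$maxRange, pre = pre)
}

#' Eligibility of candidates under the exclusion band
#'
#' A candidate is eligible as a negative iff its centroid distance lies
#' strictly outside `[minRange, maxRange]`; boundary values count as
#' inside.
#'
#' @param candidates a [PairFeatureSet-class] or matrix of candidate pair
#'   vectors.
#' @param model a [NegativeSelectionModel-class].
#' @return logical vector, one entry per candidate.
#' @export
eligibleNegatives <- function(candidates, model) {
  X <- if (methods::is(candidates, "PairFeatureSet")) pairFeatures(candidates)
       else as.matrix(candidates)
  d <- distanceToCentroid(X, model@centroid)
  d < model@minRange | d > model@maxRange
}

#' Select negative pairs from unlabeled candidates
#'
#' Keeps candidates strictly outside the exclusion band, removes any
#' candidate whose (ligand, receptor) identifier coincides with a known
#' positive, and draws a seeded uniform subsample of size `nNeg` when
#' more candidates are eligible.  If fewer are eligible a warning is
#' raised and all eligible candidates are returned.  Selected pairs are
#' labelled 0.
#'
#' @param candidates a [PairFeatureSet-class] of unlabeled candidates.
#' @param model a [NegativeSelectionModel-class].
#' @param nNeg number of negatives wanted (typically the number of
#'   positives, for class balance).
#' @param seed integer seed for the subsample.
#' @param positiveIds optional character vector of known-positive pair ids
#'   (`"ligand_receptor"`) to exclude.
#' @return a [PairFeatureSet-class] of selected negatives (labels 0).
#' @export
selectNegatives <- function(candidates, model, nNeg, seed = 1L,
                            positiveIds = character(0)) {
  .assert(nNeg >= 1L, "nNeg must be >= 1")
  ok <- eligibleNegatives(candidates, model)
  if (length(positiveIds)) ok <- ok & !(pairIds(candidates) %in% positiveIds)
  eligible <- which(ok)
  if (length(eligible) < nNeg) {
    warning(sprintf("only %d eligible negatives for nNeg = %d; returning all",
                    length(eligible), nNeg), call. = FALSE)
    pick <- eligible
  } else {
    pick <- withr::with_seed(as.integer(seed),
                             sort(sample(eligible, nNeg)))
  }
  out <- candidates[pick]
  out@y <- rep(0L, length(pick))
  message(sprintf(
    "negative selection: %d candidates, %d eligible, %d selected (band [%.4g, %.4g])",
    length(candidates), length(eligible), length(pick),
    model@minRange, model@maxRange))
  out
}
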