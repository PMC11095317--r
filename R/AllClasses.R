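#' @import methods
NULL

#' Principal-component model for protein descriptor vectors
#'
#' Holds the centering vector, the orthonormal component basis and the
#' retained dimension `d` of a PCA fitted on 3036-dimensional protein
#' descriptor vectors.  Ligand and receptor vectors are projected through
#' the same model so that concatenated pair vectors live in one
#' commensurable latent space.
#'
#' @slot center numeric centering vector (length = input dimension).
#' @slot rotation matrix with `d` orthonormal columns (input dim x d).
#' @slot sdev numeric standard deviations of the retained components.
#' @slot d integer, number of retained components.
#'
#' @seealso [fitProteinPCA()], [applyProteinPCA()]
#' @export
setClass("ProteinPCA",
  representation(center = "numeric", rotation = "matrix",
                 sdev = "numeric", d = "integer"))

setValidity("ProteinPCA", function(object) {
  d <- object@d
  if (length(d) != 1L || d < 1L) return("d must be a positive integer")
  if (ncol(object@rotation) != d) return("rotation must have d columns")
  if (nrow(object@rotation) != length(object@center))
    return("rotation rows must match center length")
  G <- crossprod(object@rotation)
  if (max(abs(G - diag(d))) > 1e-8)
    return("components are not orthonormal within 1e-8")
  TRUE
})

#' Centroid-distance band model for negative-pair selection
#'
#' Stores the positive-class centroid and the exclusion band
#' `[minRange, maxRange]` derived from the distances of positive pairs to
#' that centroid.  Candidates whose centroid distance falls strictly
#' outside the band are eligible negatives.
#'
#' @slot centroid numeric, coordinate-wise mean of the positive pair
#'   vectors (length 2d).
#' @slot minDis,maxDis numeric, smallest/largest positive-to-centroid
#'   distance.
#' @slot disLen numeric, `maxDis - minDis`.
#' @slot minRange,maxRange numeric, exclusion band bounds.
#' @slot pre numeric in `[0, 1]`, band width parameter; `pre = 1` keeps the
#'   full `[minDis, maxDis]` band, `pre = 0` collapses it to the midpoint.
#'
#' @seealso [buildNegativeSelectionModel()], [selectNegatives()]
#' @export
setClass("NegativeSelectionModel",
  representation(centroid = "numeric", minDis = "numeric", maxDis = "numeric",
                 disLen = "numeric", minRange = "numeric", maxRange = "numeric",
                 pre = "numeric"))

setValidity("NegativeSelectionModel", function(object) {
  with_tol <- function(a, b) a <= b + 1e-12
  if (object@pre < 0 || object@pre > 1) return("pre must lie in [0, 1]")
  if (!with_tol(object@minDis, object@minRange)) return("minDis must be <= minRange")
  if (!with_tol(object@minRange, object@maxRange)) return("minRange must be <= maxRange")
  if (!with_tol(object@maxRange, object@maxDis)) return("maxRange must be <= maxDis")
  if (abs(object@disLen - (object@maxDis - object@minDis)) > 1e-9)
    return("disLen must equal maxDis - minDis")
  TRUE
})

#' Set of ligand-receptor pair feature vectors
#'
#' A matrix of concatenated ligand|receptor feature vectors (one row per
#' pair, width 2d) together with the pair identifiers and an optional
#' 0/1 interaction label per row (`NA` for unlabeled candidates).
#'
#' @slot ligandId,receptorId character vectors of pair member identifiers.
#' @slot x numeric matrix, one pair vector per row.
#' @slot y integer labels in \{0, 1\} or `NA` for unlabeled pairs.
#'
#' @seealso [buildPairFeatures()], [makePairVector()]
#' @export
setClass("PairFeatureSet",
  representation(ligandId = "character", receptorId = "character",
                 x = "matrix", y = "integer"))

setValidity("PairFeatureSet", function(object) {
  n <- nrow(object@x)
  if (length(object@ligandId) != n || length(object@receptorId) != n ||
      length(object@y) != n)
    return("ligandId, receptorId and y must match the number of rows of x")
  lab <- object@y[!is.na(object@y)]
  if (length(lab) && !all(lab %in% c(0L, 1L)))
    return("labels must be 0, 1 or NA")
  if (any(!is.finite(object@x))) return("pair features must be finite")
  TRUE
})

#' @describeIn PairFeatureSet number of pairs in the set.
#' @param x a `PairFeatureSet`.
#' @export
setMethod("length", "PairFeatureSet", function(x) nrow(x@x))

#' @describeIn PairFeatureSet subset pairs by index.
#' @param i integer or logical index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PairFeatureSet", function(x, i, j, ..., drop = FALSE) {
  new("PairFeatureSet", ligandId = x@ligandId[i], receptorId = x@receptorId[i],
      x = x@x[i, , drop = FALSE], y = x@y[i])
})

#' Extract the feature matrix of a PairFeatureSet
#' @param object a `PairFeatureSet`.
#' @return numeric matrix, one pair vector per row.
#' @export
pairFeatures <- function(object) object@x

#' Extract the labels of a PairFeatureSet
#' @param object a `PairFeatureSet`.
#' @return integer vector of 0/1 labels with `NA` for unlabeled pairs.
#' @export
pairLabels <- function(object) object@y

#' Extract "ligand_receptor" pair identifiers
#' @param object a `PairFeatureSet`.
#' @return character vector of combined pair ids.
#' @export
pairIds <- function(object) paste(object@ligandId, object@receptorId, sep = "_")

#' Trained stacking ensemble for LRI classification
#'
#' Three base learners (SVM, 1D-CNN, multi-head attention, in that fixed
#' order) trained on the basic 70\% split, plus a softmax meta-perceptron
#' trained on the six base-learner class scores computed on the 30\%
#' meta split.
#'
#' @slot base list of the three trained base learners.
#' @slot meta trained meta-perceptron (internal network representation).
#' @slot config learner configuration list (see [defaultLearnerConfig()]).
#' @slot splitSeed integer seed that produced the 70/30 split.
#' @slot basicIdx,metaIdx integer row indices of the two split parts.
#'
#' @seealso [fitStacking()], [predictProba()]
#' @export
setClass("StackedLRIModel",
  representation(base = "list", meta = "list", config = "list",
                 splitSeed = "integer", basicIdx = "integer",
                 metaIdx = "integer"))

setValidity("StackedLRIModel", function(object) {
  if (length(object@base) != 3L) return("exactly three base learners required")
  kinds <- vapply(object@base, function(b) b$kind, character(1))
  if (!identical(kinds, c("svm", "cnn", "mha")))
    return("base learners must be ordered svm, cnn, mha")
  TRUE
})

#' Result of cell-cell communication inference
#'
#' Per-method m x m communication matrices (cell expression, expression
#' product, specific expression), their min-max normalized counterparts,
#' the final three-point (PERT) combined strength matrix, the filtered
#' interaction table, and per-interaction ligand/receptor factors from
#' which per-pair rankings are reconstructed.
#'
#' @slot raw list of three m x m score matrices (methods `cell`,
#'   `product`, `specific`).
#' @slot normalized list of the three min-max normalized matrices.
#' @slot strength final m x m matrix, `(g_max + 4 g_med + g_min) / 6`
#'   element-wise over the normalized matrices.
#' @slot lris data.frame of interactions surviving the filter.
#' @slot ligandFactors,receptorFactors lists of v x m matrices per method;
#'   the contribution of interaction i to the (j, p) entry is
#'   `ligandFactors[i, j] * receptorFactors[i, p]`.
#' @slot cellTypes character vector of the m cell-type names.
#'
#' @seealso [inferCCC()], [topLris()], [cccEdgeList()]
#' @export
setClass("CCCResult",
  representation(raw = "list", normalized = "list", strength = "matrix",
                 lris = "data.frame", ligandFactors = "list",
                 receptorFactors = "list", cellTypes = "character"))

setValidity("CCCResult", function(object) {
  m <- length(object@cellTypes)
  ok <- function(M) is.matrix(M) && all(dim(M) == c(m, m))
  if (!all(vapply(object@raw, ok, logical(1)))) return("raw matrices must be m x m")
  if (!all(vapply(object@normalized, ok, logical(1))))
    return("normalized matrices must be m x m")
  if (!ok(object@strength)) return("strength must be m x m")
  g <- unlist(object@normalized)
  if (length(g) && (min(g) < -1e-9 || max(g) > 1 + 1e-9))
    return("normalized scores must lie in [0, 1]")
  TRUE
})

#' Extract the final communication strength matrix
#' @param object a `CCCResult`.
#' @return m x m numeric matrix of sender-by-receiver strengths.
#' @export
cccStrength <- function(object) object@strength

#' Extract per-method communication matrices
#' @param object a `CCCResult`.
#' @param normalized logical; return the min-max normalized matrices?
#' @return named list of three m x m matrices.
#' @export
cccMatrices <- function(object, normalized = FALSE) {
  if (normalized) object@normalized else object@raw
}

#' Extract the filtered interaction table
#' @param object a `CCCResult`.
#' @return data.frame with columns `ligand`, `receptor`, `probability`,
#'   `source`.
#' @export
filteredLris <- function(object) object@lris

#' @exportMethod show
setMethod("show", "ProteinPCA", function(object) {
  cat(sprintf("ProteinPCA: %d -> %d dimensions\n",
              nrow(object@rotation), object@d))
  cat(sprintf("  top component sdev: %.4g\n", object@sdev[1L]))
})

setMethod("show", "NegativeSelectionModel", function(object) {
  cat(sprintf(
    "NegativeSelectionModel (pre = %.3g)\n  distance span [%.4g, %.4g]\n  exclusion band [%.4g, %.4g]\n",
    object@pre, object@minDis, object@maxDis, object@minRange, object@maxRange))
})

setMethod("show", "PairFeatureSet", function(object) {
  n <- length(object)
  lab <- object@y
  cat(sprintf("PairFeatureSet: %d pairs, width %d (%d positive, %d negative, %d unlabeled)\n",
              n, ncol(object@x), sum(lab == 1L, na.rm = TRUE),
              sum(lab == 0L, na.rm = TRUE), sum(is.na(lab))))
})

setMethod("show", "StackedLRIModel", function(object) {
  cat("StackedLRIModel: base learners svm + cnn + mha, softmax meta-perceptron\n")
  cat(sprintf("  split: %d basic / %d meta samples (seed %d)\n",
              length(object@basicIdx), length(object@metaIdx), object@splitSeed))
})

setMethod("show", "CCCResult", function(object) {
  m <- length(object@cellTypes)
  cat(sprintf("CCCResult: %d cell types, %d filtered interactions\n",
              m, nrow(object@lris)))
  if (m) {
    top <- which(object@strength == max(object@strength), arr.ind = TRUE)[1L, ]
    cat(sprintf("  strongest link: %s -> %s (%.3f)\n",
                object@cellTypes[top[1L]], object@cellTypes[top[2L]],
                max(object@strength)))
  }
})
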