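## LRI filtering against expression data and cell-cell communication
## strength between cell types: three per-pair scores (cell expression,
## expression product, specific expression) summed over filtered LRIs,
## min-max normalized per method and combined element-wise with the PERT
## three-point estimate.

#' Build an ExpressionDataset
#'
#' Wraps a genes x cells expression matrix and per-cell type labels in a
#' [SummarizedExperiment::SummarizedExperiment] (assay `"counts"`,
#' `colData$cell_type`), the container all CCC scoring operates on.
#'
#' @param mat non-negative numeric matrix, genes x cells, with unique
#'   gene rownames.
#' @param cellType character/factor vector of cell-type labels, one per
#'   cell.
#' @return a `SummarizedExperiment`.
#' @export
expressionDataset <- function(mat, cellType) {
  mat <- as.matrix(mat)
  .assert(!is.null(rownames(mat)) && !anyDuplicated(rownames(mat)),
          "expression matrix needs unique gene rownames")
  .assert(length(cellType) == ncol(mat),
          "one cell-type label per cell required (%d labels, %d cells)",
          length(cellType), ncol(mat))
  .assert(all(mat >= 0), "expression values must be non-negative")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("cell", seq_len(ncol(mat)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    colData = S4Vectors::DataFrame(cell_type = as.character(cellType),
                                   row.names = colnames(mat)))
}

#' Cell-type labels of an ExpressionDataset
#' @param expr a `SummarizedExperiment` built by [expressionDataset()].
#' @return character vector of per-cell labels.
#' @export
cellTypes <- function(expr) {
  as.character(SummarizedExperiment::colData(expr)$cell_type)
}

.exprMatrix <- function(expr) SummarizedExperiment::assay(expr, "counts")

## per-gene per-type summaries: fraction of cells with expression > 0 and
## arithmetic mean including zeros
.typeSummaries <- function(expr) {
  M <- .exprMatrix(expr)
  ct <- cellTypes(expr)
  types <- sort(unique(ct))
  frac <- mean_ <- matrix(0, nrow(M), length(types),
                          dimnames = list(rownames(M), types))
  for (tt in types) {
    sel <- ct == tt
    frac[, tt] <- rowMeans(M[, sel, drop = FALSE] > 0)
    mean_[, tt] <- rowMeans(M[, sel, drop = FALSE])
  }
  list(types = types, frac = frac, mean = mean_)
}

#' Filter an interaction table against a probability threshold and
#' expression data
#'
#' Predicted interactions are kept iff `probability > theta` (strictly);
#' known interactions bypass the threshold.  Any interaction whose ligand
#' or receptor gene is absent from the expression matrix, or expressed in
#' no cell, is dropped.  Duplicated (ligand, receptor) pairs are
#' deduplicated keeping `source = "known"` preferentially.
#'
#' @param lris data.frame with columns `ligand`, `receptor`,
#'   `probability` (may be `NA` for known entries) and `source`
#'   (`"known"` or `"predicted"`).
#' @param theta probability threshold in `[0, 1]` (default 0.99).
#' @param expr an [expressionDataset()].
#' @return the filtered data.frame.
#' @export
filterLris <- function(lris, theta = 0.99, expr) {
  .assert(theta >= 0 && theta <= 1, "theta must lie in [0, 1]")
  .assert(all(c("ligand", "receptor", "source") %in% names(lris)),
          "lris needs ligand, receptor and source columns")
  if (is.null(lris$probability)) lris$probability <- NA_real_
  known <- lris$source == "known"
  keep <- known | (!is.na(lris$probability) & lris$probability > theta)
  out <- lris[keep, , drop = FALSE]
  M <- .exprMatrix(expr)
  expressed <- rownames(M)[rowSums(M > 0) > 0]
  out <- out[out$ligand %in% expressed & out$receptor %in% expressed, ,
             drop = FALSE]
  # known first so duplicated() keeps the known copy
  out <- out[order(out$source != "known"), , drop = FALSE]
  out <- out[!duplicated(out[, c("ligand", "receptor")]), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) {
    warning("no interactions survive filtering; scores will be all zero",
            call. = FALSE)
  }
  out
}

.typeIndex <- function(expr, label) {
  types <- sort(unique(cellTypes(expr)))
  .assert(label %in% types, "unknown cell type '%s'", label)
  label
}

#' Cell-expression score of one interaction for one sender/receiver pair
#'
#' `(c_hat[u, j] / n1) * (c_hat[w, p] / n2)` where `c_hat` counts cells
#' of the type with expression > 0 and `n1`, `n2` are the type sizes;
#' lies in `[0, 1]`.
#'
#' @param u,w ligand and receptor gene ids.
#' @param j,p sender and receiver cell-type labels.
#' @param expr an [expressionDataset()].
#' @return score in `[0, 1]`.
#' @export
scoreCellExpression <- function(u, w, j, p, expr) {
  s <- .typeSummaries(expr)
  .assert(all(c(u, w) %in% rownames(s$frac)), "gene not in expression matrix")
  s$frac[u, .typeIndex(expr, j)] * s$frac[w, .typeIndex(expr, p)]
}

#' Expression-product score of one interaction
#'
#' Product of the mean ligand expression over all sender-type cells and
#' the mean receptor expression over all receiver-type cells (zeros
#' included in the means).
#'
#' @inheritParams scoreCellExpression
#' @return non-negative score.
#' @export
scoreExpressionProduct <- function(u, w, j, p, expr) {
  s <- .typeSummaries(expr)
  .assert(all(c(u, w) %in% rownames(s$mean)), "gene not in expression matrix")
  s$mean[u, .typeIndex(expr, j)] * s$mean[w, .typeIndex(expr, p)]
}

#' Specific-expression score of one interaction
#'
#' Each factor is the type mean divided by the sum of that gene's type
#' means over all m types (0 when the denominator is 0), so each factor
#' lies in `[0, 1]`.
#'
#' @inheritParams scoreCellExpression
#' @return score in `[0, 1]`.
#' @export
scoreSpecificExpression <- function(u, w, j, p, expr) {
  s <- .typeSummaries(expr)
  .assert(all(c(u, w) %in% rownames(s$mean)), "gene not in expression matrix")
  lsum <- sum(s$mean[u, ])
  rsum <- sum(s$mean[w, ])
  lf <- if (lsum > 0) s$mean[u, .typeIndex(expr, j)] / lsum else 0
  rf <- if (rsum > 0) s$mean[w, .typeIndex(expr, p)] / rsum else 0
  lf * rf
}

## per-method ligand/receptor factor matrices (v x m): the contribution of
## interaction i to entry (j, p) is L[i, j] * R[i, p]
.lriFactors <- function(expr, lris) {
  s <- .typeSummaries(expr)
  m <- length(s$types)
  v <- nrow(lris)
  zero <- matrix(0, v, m, dimnames = list(NULL, s$types))
  out <- list(
    cell = list(L = zero, R = zero),
    product = list(L = zero, R = zero),
    specific = list(L = zero, R = zero))
  if (v) {
    lig <- lris$ligand; rec <- lris$receptor
    out$cell$L <- s$frac[lig, , drop = FALSE]
    out$cell$R <- s$frac[rec, , drop = FALSE]
    out$product$L <- s$mean[lig, , drop = FALSE]
    out$product$R <- s$mean[rec, , drop = FALSE]
    normRows <- function(M) {
      rs <- rowSums(M)
      M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
      M[rs == 0, ] <- 0
      M
    }
    out$specific$L <- normRows(out$product$L)
    out$specific$R <- normRows(out$product$R)
    for (meth in names(out)) {
      dimnames(out[[meth]]$L) <- list(NULL, s$types)
      dimnames(out[[meth]]$R) <- list(NULL, s$types)
    }
  }
  out
}

#' Communication matrix for one scoring method
#'
#' Entry (j, p) is the sum over the filtered interactions of the
#' per-pair score for sender type j and receiver type p; all ordered
#' type pairs including the diagonal are computed.
#'
#' @param method one of `"cell"`, `"product"`, `"specific"`.
#' @param expr an [expressionDataset()].
#' @param lris filtered interaction data.frame (see [filterLris()]).
#' @return m x m numeric matrix with cell types as dimnames.
#' @export
cccMatrix <- function(method = c("cell", "product", "specific"), expr, lris) {
  method <- match.arg(method)
  fac <- .lriFactors(expr, lris)[[method]]
  types <- sort(unique(cellTypes(expr)))
  if (!nrow(lris)) {
    return(matrix(0, length(types), length(types),
                  dimnames = list(types, types)))
  }
  M <- crossprod(fac$L, fac$R)  # sum_i L[i, j] * R[i, p]
  dimnames(M) <- list(types, types)
  M
}

#' Min-max normalize a matrix to [0, 1]
#'
#' `(x - min) / (max - min)` over all entries; a constant matrix maps to
#' all zeros.
#'
#' @param M numeric matrix.
#' @return matrix of the same shape with entries in `[0, 1]`.
#' @export
minmaxNormalize <- function(M) {
  rng <- range(M)
  if (diff(rng) == 0) return(M * 0)
  (M - rng[1L]) / diff(rng)
}

#' PERT three-point estimate of three scores
#'
#' `(g_max + 4 g_med + g_min) / 6` after sorting; vectorized over
#' parallel entries.
#'
#' @param g1,g2,g3 numeric vectors or matrices of equal shape.
#' @return the element-wise three-point estimate, always within
#'   `[min, max]` of its inputs.
#' @examples
#' threePointEstimate(0.2, 0.9, 0.4)  # 0.45
#' @export
threePointEstimate <- function(g1, g2, g3) {
  lo <- pmin(g1, g2, g3)
  hi <- pmax(g1, g2, g3)
  med <- g1 + g2 + g3 - lo - hi
  out <- (hi + 4 * med + lo) / 6
  if (is.matrix(g1)) dimnames(out) <- dimnames(g1)
  out
}

#' Infer cell-cell communication strengths
#'
#' Filters the interaction table, computes the three per-method m x m
#' matrices, min-max normalizes each, and combines them element-wise with
#' the three-point estimate.  Per-interaction factors are stored so
#' [topLris()] can rank interactions for any sender/receiver pair.
#'
#' @param expr an [expressionDataset()] with at least two cell types.
#' @param lris interaction data.frame (see [filterLris()] for columns).
#' @param theta probability threshold for predicted interactions
#'   (default 0.99).
#' @return a [CCCResult-class].
#' @export
inferCCC <- function(expr, lris, theta = 0.99) {
  types <- sort(unique(cellTypes(expr)))
  .assert(length(types) >= 2L, "CCC inference needs at least 2 cell types")
  kept <- filterLris(lris, theta, expr)
  raw <- list(cell = cccMatrix("cell", expr, kept),
              product = cccMatrix("product", expr, kept),
              specific = cccMatrix("specific", expr, kept))
  normalized <- lapply(raw, minmaxNormalize)
  strength <- threePointEstimate(normalized$cell, normalized$product,
                                 normalized$specific)
  fac <- .lriFactors(expr, kept)
  new("CCCResult", raw = raw, normalized = normalized, strength = strength,
      lris = kept,
      ligandFactors = lapply(fac, `[[`, "L"),
      receptorFactors = lapply(fac, `[[`, "R"),
      cellTypes = types)
}

#' Top interactions mediating one sender/receiver pair
#'
#' Ranks the filtered interactions by their contribution to the (j, p)
#' entry under each scoring method and under the combined score (the
#' three-point estimate of the three per-interaction scores, each
#' min-max normalized across interactions within the pair).  Ties break
#' deterministically by (score desc, ligand asc, receptor asc).
#'
#' @param result a [CCCResult-class].
#' @param j,p sender and receiver cell-type labels.
#' @param k number of interactions to return (truncated to the available
#'   count).
#' @return data.frame with columns `rank`, `ligand`, `receptor`,
#'   `score_cell`, `score_product`, `score_specific`, `score_combined`,
#'   ordered by the combined score.
#' @export
topLris <- function(result, j, p, k = 3L) {
  .assert(k >= 1L, "k must be >= 1")
  types <- result@cellTypes
  .assert(j %in% types && p %in% types,
          "unknown cell-type pair (%s, %s)", j, p)
  v <- nrow(result@lris)
  if (!v) {
    return(data.frame(rank = integer(0), ligand = character(0),
                      receptor = character(0), score_cell = numeric(0),
                      score_product = numeric(0), score_specific = numeric(0),
                      score_combined = numeric(0)))
  }
  perMethod <- vapply(names(result@ligandFactors), function(meth) {
    result@ligandFactors[[meth]][, j] * result@receptorFactors[[meth]][, p]
  }, numeric(v))
  if (v == 1L) perMethod <- matrix(perMethod, 1L,
                                   dimnames = list(NULL,
                                                   names(result@ligandFactors)))
  normCol <- function(x) {
    r <- range(x)
    if (diff(r) == 0) x * 0 else (x - r[1L]) / diff(r)
  }
  G <- apply(perMethod, 2L, normCol)
  if (v == 1L) G <- matrix(G, 1L)
  combined <- threePointEstimate(G[, 1L], G[, 2L], G[, 3L])
  ord <- order(-combined, result@lris$ligand, result@lris$receptor)
  take <- ord[seq_len(min(k, v))]
  data.frame(rank = seq_along(take),
             ligand = result@lris$ligand[take],
             receptor = result@lris$receptor[take],
             score_cell = perMethod[take, "cell"],
             score_product = perMethod[take, "product"],
             score_specific = perMethod[take, "specific"],
             score_combined = combined[take],
             row.names = NULL)
}

#' Communication network edge list
#'
#' One row per ordered sender/receiver pair with the final strength and
#' the number of interactions contributing a positive combined score.
#'
#' @param result a [CCCResult-class].
#' @param dropDiagonal drop self-communication edges? (default FALSE).
#' @return data.frame with columns `source_type`, `target_type`,
#'   `weight`, `n_LRIs`.
#' @export
cccEdgeList <- function(result, dropDiagonal = FALSE) {
  types <- result@cellTypes
  grid <- expand.grid(target_type = types, source_type = types,
                      stringsAsFactors = FALSE)[, 2:1]
  nL <- mapply(function(j, p) {
    if (!nrow(result@lris)) return(0L)
    contrib <- Reduce(`+`, lapply(names(result@ligandFactors), function(meth) {
      result@ligandFactors[[meth]][, j] * result@receptorFactors[[meth]][, p]
    }))
    sum(contrib > 0)
  }, grid$source_type, grid$target_type)
  out <- data.frame(grid,
                    weight = result@strength[cbind(grid$source_type,
                                                   grid$target_type)],
                    n_LRIs = as.integer(nL), row.names = NULL)
  if (dropDiagonal) out <- out[out$source_type != out$target_type, ,
                               drop = FALSE]
  out
}
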