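# Small hand-checkable expression fixtures for the three scoring methods
# and the three-point combination.

# genes g1..g4 over 6 cells: types A (4 cells) and B (2 cells)
fixtureExpr <- function() {
  M <- rbind(
    g1 = c(2, 1, 3, 0, 0, 0),  # ligand expressed in 3 of 4 A cells
    g2 = c(0, 0, 0, 0, 5, 0),  # receptor expressed in 1 of 2 B cells
    g3 = c(1, 3, 1, 3, 0, 4),  # means: A = 2, B = 2
    g4 = c(0, 0, 0, 0, 2, 6))  # B-only gene
  expressionDataset(M, c("A", "A", "A", "A", "B", "B"))
}

test_that("filtering keeps predicted pairs strictly above theta and known pairs always", {
  expr <- fixtureExpr()
  lris <- data.frame(
    ligand = c("g1", "g1", "g3", "zz", "g1"),
    receptor = c("g2", "g3", "g4", "g2", "g4"),
    probability = c(0.995, 0.99, NA, 0.999, 0.2),
    source = c("predicted", "predicted", "known", "predicted", "predicted"))
  kept <- filterLris(lris, theta = 0.99, expr)
  ids <- paste(kept$ligand, kept$receptor)
  expect_true("g1 g2" %in% ids)       # 0.995 > 0.99
  expect_false("g1 g3" %in% ids)      # exactly 0.99: strict inequality
  expect_true("g3 g4" %in% ids)       # known bypasses the threshold
  expect_false("zz g2" %in% ids)      # ligand absent from the matrix
  expect_false("g1 g4" %in% ids)      # below threshold
})

test_that("duplicate pairs deduplicate keeping the known entry", {
  expr <- fixtureExpr()
  lris <- data.frame(ligand = c("g1", "g1"), receptor = c("g2", "g2"),
                     probability = c(0.999, NA),
                     source = c("predicted", "known"))
  kept <- filterLris(lris, theta = 0.99, expr)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$source, "known")
})

test_that("a gene expressed in no cell is dropped even when listed", {
  M <- rbind(g1 = c(1, 1, 1, 1), g2 = c(0, 0, 0, 0))
  expr <- expressionDataset(M, c("A", "A", "B", "B"))
  lris <- data.frame(ligand = "g1", receptor = "g2", probability = 1,
                     source = "predicted")
  expect_warning(kept <- filterLris(lris, 0.5, expr), "no interactions")
  expect_equal(nrow(kept), 0)
})

test_that("cell-expression score multiplies expressing-cell fractions", {
  expr <- fixtureExpr()
  # 3 of 4 sender cells express g1, 1 of 2 receiver cells express g2
  expect_equal(scoreCellExpression("g1", "g2", "A", "B", expr), 0.375)
  expect_equal(scoreCellExpression("g3", "g3", "A", "A", expr), 1)
  expect_equal(scoreCellExpression("g4", "g2", "A", "B", expr), 0)
  expect_error(scoreCellExpression("g1", "g2", "A", "Z", expr), "unknown")
})

test_that("expression-product score multiplies type means including zeros", {
  # toy 2-cell types: ligand values (1, 3), receptor values (0, 4)
  M <- rbind(u = c(1, 3, 0, 0), w = c(0, 0, 0, 4))
  expr <- expressionDataset(M, c("A", "A", "B", "B"))
  expect_equal(scoreExpressionProduct("u", "w", "A", "B", expr), 2 * 2)
  expect_equal(scoreExpressionProduct("w", "u", "A", "B", expr), 0)
})

test_that("specific-expression score normalizes means over all types", {
  # m=2 with ligand means (2, 6) and receptor means (1, 3)
  M <- rbind(u = c(2, 2, 6, 6), w = c(1, 1, 3, 3))
  expr <- expressionDataset(M, c("A", "A", "B", "B"))
  expect_equal(scoreSpecificExpression("u", "w", "B", "B", expr),
               0.75 * 0.75)
  # ligand expressed only in one type: that factor is 1
  M2 <- rbind(u = c(5, 4, 0, 0), w = c(1, 1, 1, 1))
  expr2 <- expressionDataset(M2, c("A", "A", "B", "B"))
  expect_equal(scoreSpecificExpression("u", "w", "A", "A", expr2), 1 * 0.5)
})

test_that("communication matrices are additive over disjoint interaction sets", {
  expr <- fixtureExpr()
  A <- data.frame(ligand = "g1", receptor = "g2", probability = 1,
                  source = "predicted")
  B <- data.frame(ligand = "g3", receptor = "g4", probability = 1,
                  source = "predicted")
  for (meth in c("cell", "product", "specific")) {
    MA <- cccMatrix(meth, expr, A)
    MB <- cccMatrix(meth, expr, B)
    MAB <- cccMatrix(meth, expr, rbind(A, B))
    expect_equal(MAB, MA + MB)
  }
  empty <- A[0, ]
  expect_equal(unname(cccMatrix("cell", expr, empty)), matrix(0, 2, 2))
})

test_that("a single interaction yields its per-pair score grid", {
  expr <- fixtureExpr()
  lris <- data.frame(ligand = "g1", receptor = "g2", probability = 1,
                     source = "predicted")
  M <- cccMatrix("cell", expr, lris)
  for (j in c("A", "B")) for (p in c("A", "B")) {
    expect_equal(M[j, p], scoreCellExpression("g1", "g2", j, p, expr))
  }
})

test_that("min-max normalization maps extremes to 0/1 and constants to zero", {
  M <- matrix(c(0, 10, 5, 5), 2, 2)
  N <- minmaxNormalize(M)
  expect_equal(range(N), c(0, 1))
  expect_equal(minmaxNormalize(rbind(c(0, 5), c(10, 5))),
               rbind(c(0, 0.5), c(1, 0.5)))
  expect_equal(minmaxNormalize(matrix(3, 2, 2)), matrix(0, 2, 2))
})

test_that("three-point estimation weights the median four-fold", {
  expect_equal(threePointEstimate(0.7, 0.7, 0.7), 0.7)
  expect_equal(threePointEstimate(0, 0.5, 1), 0.5)
  expect_equal(threePointEstimate(0.2, 0.9, 0.4), 0.45)
  # element-wise over matrices, result within [min, max]
  withr::with_seed(2, {
    g1 <- matrix(runif(9), 3); g2 <- matrix(runif(9), 3)
    g3 <- matrix(runif(9), 3)
  })
  f <- threePointEstimate(g1, g2, g3)
  expect_true(all(f >= pmin(g1, g2, g3) - 1e-12 &
                  f <= pmax(g1, g2, g3) + 1e-12))
})

test_that("inferCCC recovers planted communication and keeps strengths in [0, 1]", {
  ex <- genExpression(synthSpec(seed = 1))
  res <- inferCCC(ex$expr, ex$lris, theta = 0.99)
  f <- cccStrength(res)
  expect_true(all(f >= 0 & f <= 1))
  am <- which(f == max(f), arr.ind = TRUE)[1, ]
  expect_equal(res@cellTypes[am[1]], ex$planted$sender)
  expect_equal(res@cellTypes[am[2]], ex$planted$receiver)
  top <- topLris(res, ex$planted$sender, ex$planted$receiver, k = 3)
  expect_equal(top$ligand[1], ex$planted$ligand)
  expect_equal(top$receptor[1], ex$planted$receptor)
})

test_that("uniform expression yields a degenerate all-zero strength matrix", {
  M <- matrix(1, 4, 6, dimnames = list(paste0("g", 1:4), NULL))
  expr <- expressionDataset(M, rep(c("A", "B"), each = 3))
  lris <- data.frame(ligand = "g1", receptor = "g2", probability = 1,
                     source = "predicted")
  res <- inferCCC(expr, lris)
  expect_equal(unname(cccStrength(res)), matrix(0, 2, 2))
})

test_that("cell-id relabeling leaves matrices unchanged; matrix scaling leaves the result invariant", {
  ex <- genExpression(synthSpec(seed = 6))
  M <- SummarizedExperiment::assay(ex$expr)
  ct <- cellTypes(ex$expr)
  res1 <- inferCCC(ex$expr, ex$lris)
  M2 <- M; colnames(M2) <- paste0("renamed", seq_len(ncol(M)))
  res2 <- inferCCC(expressionDataset(M2, ct), ex$lris)
  expect_equal(res1@raw, res2@raw)
  # scaling all counts by c > 0: cell and specific scores unchanged,
  # product scales, min-max restores -> final strength invariant
  res3 <- inferCCC(expressionDataset(M * 7, ct), ex$lris)
  expect_equal(res1@raw$cell, res3@raw$cell)
  expect_equal(res1@raw$specific, res3@raw$specific)
  expect_equal(res1@normalized$product, res3@normalized$product)
  expect_equal(cccStrength(res1), cccStrength(res3))
})

test_that("top-interaction rankings truncate, handle singletons and break ties deterministically", {
  expr <- fixtureExpr()
  single <- data.frame(ligand = "g1", receptor = "g2", probability = 1,
                       source = "predicted")
  res <- inferCCC(expr, single)
  top <- topLris(res, "A", "B", k = 5)
  expect_equal(nrow(top), 1)
  expect_equal(top$rank, 1L)
  expect_error(topLris(res, "A", "Z"), "unknown")
  expect_error(topLris(res, "A", "B", k = 0), "k must be")
})

test_that("the edge list covers all ordered type pairs with the final weights", {
  ex <- genExpression(synthSpec(seed = 2))
  res <- inferCCC(ex$expr, ex$lris)
  edges <- cccEdgeList(res)
  m <- length(res@cellTypes)
  expect_equal(nrow(edges), m * m)
  expect_equal(
    edges$weight[edges$source_type == ex$planted$sender &
                 edges$target_type == ex$planted$receiver],
    max(cccStrength(res)))
  expect_true(all(edges$n_LRIs >= 0))
  expect_equal(nrow(cccEdgeList(res, dropDiagonal = TRUE)), m * m - m)
})
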