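test_that("sanitizeSequence folds case, strips non-canonical residues and rejects empty results", {
  expect_identical(sanitizeSequence("acde"), "ACDE")
  expect_warning(out <- sanitizeSequence("AXC", id = "p1"), "p1")
  expect_identical(out, "AC")
  expect_error(suppressWarnings(sanitizeSequence("UU", id = "p2")), "p2")
  expect_error(sanitizeSequence(""), "non-empty")
})

test_that("AAC gives residue frequencies in fixed alphabetical order", {
  v <- encodeAAC("AAAA")
  expect_equal(unname(v[1]), 1)
  expect_equal(sum(v), 1)
  expect_equal(unname(encodeAAC("ACDEFGHIKLMNPQRSTVWY")), rep(0.05, 20))
  g <- encodeAAC("GGGC")
  expect_equal(unname(g[c("AAC.G", "AAC.C")]), c(0.75, 0.25))
  expect_error(encodeAAC(""))
})

test_that("CKSAAP scores gapped pairs per block with the valid-pair denominator", {
  v <- encodeCKSAAP("AA", gaps = 0)
  expect_length(v, 400)
  expect_equal(unname(v[["CKSAAP.k0.A.A"]]), 1)
  expect_equal(sum(v), 1)
  v1 <- encodeCKSAAP("ACA", gaps = 0:1)
  expect_equal(unname(v1[["CKSAAP.k1.A.A"]]), 1)
  expect_equal(sum(v1[401:800]), 1)
  expect_length(encodeCKSAAP(strrep("ACDG", 10)), 2400)
  expect_error(encodeCKSAAP("ACDEFG"), ">= 7")
})

test_that("every CKSAAP gap block sums to 1 on random sequences", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      v <- encodeCKSAAP(randomSeq(sample(10:80, 1)))
      sums <- vapply(0:5, function(k) sum(v[k * 400 + 1:400]), numeric(1))
      expect_equal(sums, rep(1, 6))
    }
  })
})

test_that("CTD homopolymer has zero transitions and unit composition in the residue's group", {
  v <- encodeCTD(strrep("A", 10))
  expect_length(v, 273)
  expect_equal(unname(v[40:78]), rep(0, 39))  # transition block
  lut <- stackCCC:::.ctdLookup
  comp <- v[1:39]
  for (i in seq_along(lut)) {
    gA <- lut[[i]][1]  # group of alanine for property i
    expected <- c(0, 0, 0); expected[gA] <- 1
    expect_equal(unname(comp[(i - 1) * 3 + 1:3]), expected)
  }
})

test_that("CTD invariants hold: distributions in [0, 100], compositions sum to 1 per property", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      v <- encodeCTD(randomSeq(sample(5:60, 1)))
      comp <- matrix(v[1:39], nrow = 3)
      expect_equal(colSums(comp), rep(1, 13))
      expect_true(all(v[79:273] >= 0 & v[79:273] <= 100))
    }
  })
  expect_error(encodeCTD("A"), ">= 2")
})

test_that("conjoint triad counts class triples and normalizes by L - 2", {
  v <- encodeCTriad("AAAA")
  expect_length(v, 343)
  expect_equal(sum(v > 0), 1)
  expect_equal(max(v), 1)
  expect_error(encodeCTriad("AA"), ">= 3")
  withr::with_seed(8, expect_equal(sum(encodeCTriad(randomSeq(40))), 1))
})

test_that("full protein encoding is the 3036-long AAC|CKSAAP|CTD|CTriad concatenation", {
  s <- withr::with_seed(3, randomSeq(60))
  v <- encodeProtein(s)
  expect_length(v, 3036)
  expect_equal(unname(v[1:20]), unname(encodeAAC(s)))
  layout <- featureBlockLayout()
  expect_equal(sum(layout), 3036L)
  expect_equal(unname(layout), c(20L, 2400L, 273L, 343L))
  expect_true(all(is.finite(v)))
  expect_error(encodeProtein("ACD", id = "tiny"), "tiny")
})

test_that("encoders match independent brute-force enumerators on random short sequences", {
  withr::with_seed(123, {
    for (rep in 1:15) {
      s <- randomSeq(sample(8:40, 1))
      expect_equal(unname(encodeCKSAAP(s)), oracleCKSAAP(s), tolerance = 1e-12)
      expect_equal(unname(encodeCTD(s)), oracleCTD(s), tolerance = 1e-12)
      expect_equal(unname(encodeCTriad(s)), oracleCTriad(s), tolerance = 1e-12)
    }
  })
})

test_that("PCA centres the data, is deterministic and reconstructs a rank-2 matrix exactly", {
  withr::with_seed(5, {
    basis <- matrix(rnorm(6), 3, 2)
    scores <- matrix(rnorm(40), 20, 2)
    X <- scores %*% t(basis)  # rank-2 data in 3 dimensions
  })
  m <- fitProteinPCA(X, 2)
  expect_equal(as.numeric(applyProteinPCA(m, colMeans(X))), c(0, 0))
  Xr <- inverseProteinPCA(m, applyProteinPCA(m, X))
  expect_lt(max(abs(Xr - X)), 1e-8)
  # oracle: explicit eigendecomposition of the 3x3 covariance
  ev <- eigen(cov(X))$vectors[, 1:2]
  for (j in 1:2) {
    expect_equal(abs(sum(m@rotation[, j] * ev[, j])), 1, tolerance = 1e-8)
  }
  # deterministic sign convention: largest-magnitude loading positive
  for (j in 1:2) expect_gt(m@rotation[which.max(abs(m@rotation[, j])), j], 0)
  m2 <- fitProteinPCA(X, 2)
  expect_identical(m@rotation, m2@rotation)
  expect_error(fitProteinPCA(X, 10), "d must be")
})

test_that("PCA explained variance is non-increasing and reconstruction improves with d", {
  X <- withr::with_seed(9, matrix(rnorm(50 * 8), 50, 8))
  m <- fitProteinPCA(X, 8)
  expect_true(all(diff(m@sdev) <= 1e-12))
  errs <- vapply(c(2, 4, 8), function(d) {
    md <- fitProteinPCA(X, d)
    sum((inverseProteinPCA(md, applyProteinPCA(md, X)) - X)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("pair vectors concatenate ligand first and demand equal widths", {
  expect_equal(makePairVector(c(1, 2), c(3, 4)), c(1, 2, 3, 4))
  expect_false(isTRUE(all.equal(makePairVector(c(1, 2), c(3, 4)),
                                makePairVector(c(3, 4), c(1, 2)))))
  expect_error(makePairVector(1:3, 1:2), "differ in length")
})

test_that("buildPairFeatures assembles labelled 2d-wide rows from reduced vectors", {
  red <- matrix(1:8, 4, 2, dimnames = list(paste0("p", 1:4), NULL))
  tab <- data.frame(ligand_id = c("p1", "p3"), receptor_id = c("p2", "p4"),
                    label = c(1L, 0L))
  pf <- buildPairFeatures(tab, red)
  expect_s4_class(pf, "PairFeatureSet")
  expect_equal(ncol(pairFeatures(pf)), 4)
  expect_equal(pairFeatures(pf)[1, ], c(red["p1", ], red["p2", ]))
  expect_equal(pairLabels(pf), c(1L, 0L))
  expect_error(buildPairFeatures(data.frame(ligand_id = "zz",
                                            receptor_id = "p1"), red), "zz")
})
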