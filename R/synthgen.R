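## Seeded generators for every synthetic fixture the pipeline consumes:
## random protein sequences, a positive/unlabeled pair-feature geometry
## with ground-truth labels, and expression matrices with planted
## sender-receiver communication.

#' Synthetic-data specification
#'
#' Bundles the generator parameters with their defaults: 200 positive
#' pairs, 400 unlabeled candidates (25\% near-cluster decoys emulating
#' hidden positives, the rest true negatives at `separation` sigma from
#' the positive cluster), 4-dimensional pair geometry, and an expression
#' matrix of 60 genes over 3 balanced cell types of 50 cells with one
#' planted ligand/receptor pair over-expressed 10-fold between an
#' ordered sender/receiver type pair.
#'
#' @param seed integer root seed.
#' @param nPos,nUnlabeled numbers of positive and unlabeled pairs.
#' @param featureDim pair-feature dimensionality (>= 2).
#' @param separation distance between the positive and true-negative
#'   cluster centres, in units of the within-cluster standard deviation.
#' @param decoyFrac fraction of unlabeled candidates drawn from the
#'   positive cluster (hidden positives).
#' @param mTypes,cellsPerType,nGenes expression-matrix dimensions.
#' @param planted data.frame with columns `ligand`, `receptor`, `sender`,
#'   `receiver`, `effect` (multiplier > 1).
#' @return list of class `synthSpec`.
#' @export
synthSpec <- function(seed = 1L, nPos = 200L, nUnlabeled = 400L,
                      featureDim = 4L, separation = 4, decoyFrac = 0.25,
                      mTypes = 3L, cellsPerType = 50L, nGenes = 60L,
                      planted = data.frame(ligand = "gene1",
                                           receptor = "gene2",
                                           sender = "type1",
                                           receiver = "type2",
                                           effect = 10)) {
  .assert(nPos >= 1L && nUnlabeled >= 1L && featureDim >= 2L,
          "counts must be positive and featureDim >= 2")
  .assert(separation >= 0, "separation must be >= 0")
  .assert(all(planted$effect > 1), "planted effect multipliers must be > 1")
  structure(list(seed = as.integer(seed), nPos = as.integer(nPos),
                 nUnlabeled = as.integer(nUnlabeled),
                 featureDim = as.integer(featureDim),
                 separation = separation, decoyFrac = decoyFrac,
                 mTypes = as.integer(mTypes),
                 cellsPerType = as.integer(cellsPerType),
                 nGenes = as.integer(nGenes), planted = planted),
            class = "synthSpec")
}

#' Generate random protein sequences
#'
#' Residues are drawn uniformly over the 20 canonical letters; lengths
#' are uniform in `[lenMin, lenMax]`.  `lenMin >= 8` satisfies every
#' encoder's minimum-length precondition.
#'
#' @param n number of sequences.
#' @param lenMin,lenMax length bounds (`lenMin >= 8`).
#' @param seed integer seed.
#' @param prefix identifier prefix (default `"prot"`).
#' @return a [Biostrings::AAStringSet] with names `prefix1..prefixN`.
#' @export
genSequences <- function(n, lenMin = 50L, lenMax = 200L, seed = 1L,
                         prefix = "prot") {
  .assert(lenMin >= 8L, "lenMin must be >= 8 (encoder minima)")
  .assert(lenMax >= lenMin, "lenMax must be >= lenMin")
  seqs <- withr::with_seed(as.integer(seed), {
    lens <- sample(lenMin:lenMax, n, replace = TRUE)
    vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
      character(1))
  })
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- paste0(prefix, seq_len(n))
  out
}

#' Generate a positive/unlabeled pair-classification geometry
#'
#' Positives are a Gaussian cluster (sd 1 per coordinate) at the origin.
#' Unlabeled candidates are a mixture of true negatives centred
#' `separation` away (the shift spread evenly over all coordinates) and
#' near-cluster decoys drawn from the positive distribution.  The hidden
#' ground-truth label of every unlabeled candidate is returned for
#' oracle testing.
#'
#' @param spec a [synthSpec()].
#' @return list with `positives` (a [PairFeatureSet-class], labels 1),
#'   `unlabeled` (labels `NA`) and `truth` (0/1 vector for the unlabeled
#'   candidates; 1 = decoy from the positive cluster).
#' @export
genPairClassification <- function(spec) {
  d <- spec$featureDim
  shift <- rep(spec$separation / sqrt(d), d)
  withr::with_seed(spec$seed, {
    pos <- matrix(stats::rnorm(spec$nPos * d), spec$nPos, d)
    nDecoy <- round(spec$nUnlabeled * spec$decoyFrac)
    nNeg <- spec$nUnlabeled - nDecoy
    neg <- matrix(stats::rnorm(nNeg * d), nNeg, d) +
      matrix(shift, nNeg, d, byrow = TRUE)
    decoy <- matrix(stats::rnorm(nDecoy * d), nDecoy, d)
    unl <- rbind(neg, decoy)
    truth <- c(rep(0L, nNeg), rep(1L, nDecoy))
    ord <- sample(nrow(unl))
    unl <- unl[ord, , drop = FALSE]
    truth <- truth[ord]
    list(
      positives = new("PairFeatureSet",
                      ligandId = paste0("L", seq_len(spec$nPos)),
                      receptorId = paste0("R", seq_len(spec$nPos)),
                      x = pos, y = rep(1L, spec$nPos)),
      unlabeled = new("PairFeatureSet",
                      ligandId = paste0("uL", seq_len(spec$nUnlabeled)),
                      receptorId = paste0("uR", seq_len(spec$nUnlabeled)),
                      x = unl, y = rep(NA_integer_, spec$nUnlabeled)),
      truth = truth)
  })
}

#' Generate a labelled two-class feature matrix
#'
#' Convenience wrapper around the same geometry for supervised learner
#' tests: class 0 at the origin, class 1 shifted by `separation`, equal
#' sizes, shuffled.
#'
#' @param n total number of samples (split evenly).
#' @param d feature dimension.
#' @param separation class-centre distance in sigma units.
#' @param seed integer seed.
#' @return list with `X` (n x d matrix) and `y` (0/1 labels).
#' @export
genTwoClassData <- function(n = 400L, d = 400L, separation = 4, seed = 1L) {
  shift <- rep(separation / sqrt(d), d)
  withr::with_seed(as.integer(seed), {
    n1 <- n %/% 2L
    n0 <- n - n1
    X <- rbind(matrix(stats::rnorm(n0 * d), n0, d),
               matrix(stats::rnorm(n1 * d), n1, d) +
                 matrix(shift, n1, d, byrow = TRUE))
    y <- c(rep(0L, n0), rep(1L, n1))
    ord <- sample(n)
    list(X = X[ord, , drop = FALSE], y = y[ord])
  })
}

#' Generate an expression matrix with planted communication
#'
#' Baseline counts are Poisson(1) per gene and cell.  For every planted
#' interaction the ligand's rate is multiplied by `effect` in
#' sender-type cells and the receptor's rate by `effect` in
#' receiver-type cells (multiplicative on the rate, so "expressed =
#' value > 0" stays meaningful).  Cell-type labels are balanced.
#'
#' @param spec a [synthSpec()]; `nGenes` must cover all planted genes.
#' @return list with `expr` (an [expressionDataset()]), `planted` (the
#'   planted table) and `lris` (an interaction table containing the
#'   planted pairs plus background gene pairs, all with probability 1
#'   and source `"predicted"`).
#' @export
genExpression <- function(spec) {
  genes <- paste0("gene", seq_len(spec$nGenes))
  types <- paste0("type", seq_len(spec$mTypes))
  bad <- setdiff(c(spec$planted$ligand, spec$planted$receptor), genes)
  .assert(length(bad) == 0L, "planted genes not in gene list: %s",
          paste(bad, collapse = ", "))
  .assert(all(spec$planted$sender %in% types) &&
            all(spec$planted$receiver %in% types),
          "planted cell types outside type1..type%d", spec$mTypes)
  cellType <- rep(types, each = spec$cellsPerType)
  nCells <- length(cellType)
  withr::with_seed(spec$seed, {
    lambda <- matrix(1, spec$nGenes, nCells, dimnames = list(genes, NULL))
    for (i in seq_len(nrow(spec$planted))) {
      pl <- spec$planted[i, ]
      lambda[pl$ligand, cellType == pl$sender] <-
        lambda[pl$ligand, cellType == pl$sender] * pl$effect
      lambda[pl$receptor, cellType == pl$receiver] <-
        lambda[pl$receptor, cellType == pl$receiver] * pl$effect
    }
    counts <- matrix(stats::rpois(length(lambda), lambda), spec$nGenes,
                     nCells, dimnames = list(genes, NULL))
    expr <- expressionDataset(counts, cellType)
    # background pairs among non-planted genes (deterministic pairing)
    bg <- setdiff(genes, c(spec$planted$ligand, spec$planted$receptor))
    nbg <- min(10L, length(bg) %/% 2L)
    lris <- rbind(
      data.frame(ligand = spec$planted$ligand,
                 receptor = spec$planted$receptor,
                 probability = 1, source = "predicted"),
      if (nbg) data.frame(ligand = bg[seq_len(nbg)],
                          receptor = bg[nbg + seq_len(nbg)],
                          probability = 1, source = "predicted"))
    list(expr = expr, planted = spec$planted, lris = lris)
  })
}
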