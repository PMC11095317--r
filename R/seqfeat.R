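## Protein sequence descriptor encoders: four families (AAC, CKSAAP, CTD,
## conjoint triad) concatenated to a 3036-dimensional vector per protein,
## PCA reduction to d dimensions, and ligand|receptor pair vectors of
## width 2d.

#' Sanitize a raw amino-acid sequence
#'
#' Uppercases the sequence and strips any character outside the 20
#' canonical amino-acid letters (e.g. `X`, `B`, `U`, gaps), with one
#' warning per removed character type.
#'
#' @param raw character scalar, the raw sequence.
#' @param id optional record identifier used in messages.
#' @return sanitized sequence string.
#' @examples
#' sanitizeSequence("acde")           # "ACDE"
#' suppressWarnings(sanitizeSequence("AXC"))  # "AC"
#' @export
sanitizeSequence <- function(raw, id = "<sequence>") {
  .assert(is.character(raw) && length(raw) == 1L && nzchar(raw),
          "record %s: sequence must be a non-empty string", id)
  s <- toupper(raw)
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  for (b in bad) {
    warning(sprintf("record %s: removed non-canonical residue '%s'", id, b),
            call. = FALSE)
  }
  kept <- chars[chars %in% AA_ALPHABET]
  if (!length(kept)) {
    stop(sprintf("record %s: sequence empty after sanitization", id),
         call. = FALSE)
  }
  paste(kept, collapse = "")
}

.seqChars <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  .assert(all(chars %in% AA_ALPHABET),
          "sequence contains non-canonical residues; sanitize first")
  chars
}

#' Amino-acid composition (AAC) descriptor
#'
#' Per-residue frequency over the fixed alphabetical residue order
#' (`ACDEFGHIKLMNPQRSTVWY`); the 20 entries sum to 1.
#'
#' @param seq sanitized amino-acid sequence.
#' @return named numeric vector of length 20.
#' @examples
#' encodeAAC("GGGC")["G"]  # 0.75
#' @export
encodeAAC <- function(seq) {
  chars <- .seqChars(seq)
  .assert(length(chars) >= 1L, "AAC requires a non-empty sequence")
  counts <- table(factor(chars, levels = AA_ALPHABET))
  out <- as.numeric(counts) / length(chars)
  names(out) <- paste0("AAC.", AA_ALPHABET)
  out
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each gap k, the 400 ordered residue pairs separated by k
#' intervening residues are scored `count / (L - k - 1)`, so each gap
#' block is a distribution.  Blocks are ordered k = 0, 1, ..., and the
#' default gaps 0..5 give a 2400-dimensional vector.
#'
#' @param seq sanitized amino-acid sequence, length >= max(gaps) + 2.
#' @param gaps integer vector of gaps (default `0:5`).
#' @return named numeric vector of length `400 * length(gaps)`.
#' @export
encodeCKSAAP <- function(seq, gaps = 0:5) {
  chars <- .seqChars(seq)
  L <- length(chars)
  kmax <- max(gaps)
  .assert(L >= kmax + 2L,
          "CKSAAP with max gap %d requires sequence length >= %d (got %d)",
          kmax, kmax + 2L, L)
  idx <- match(chars, AA_ALPHABET)
  pairNames <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste, sep = ".")))
  out <- numeric(0)
  for (k in gaps) {
    first <- idx[seq_len(L - k - 1L)]
    second <- idx[seq_len(L - k - 1L) + k + 1L]
    # ordered pair code with first residue major, matching pairNames order
    code <- (first - 1L) * 20L + second
    counts <- tabulate(code, nbins = 400L)
    block <- counts / (L - k - 1L)
    names(block) <- paste0("CKSAAP.k", k, ".", pairNames)
    out <- c(out, block)
  }
  out
}

#' Composition/transition/distribution (CTD) descriptor
#'
#' Thirteen physicochemical properties each partition the residues into 3
#' groups.  Composition (13 x 3 = 39) gives group fractions; transition
#' (13 x 3 = 39) gives the fraction of adjacent positions whose residues
#' fall in the unordered group pairs (1,2), (1,3), (2,3); distribution
#' (13 x 3 x 5 = 195) gives, per group, the sequence positions (as a
#' percentage of the length) of the first and the 25/50/75/100\%
#' occurrence landmarks.  A group absent from the sequence yields five
#' zero distribution entries.  Blocks are concatenated C | T | D
#' (property-major within each block) for 273 features.
#'
#' @param seq sanitized amino-acid sequence, length >= 2.
#' @return named numeric vector of length 273.
#' @export
encodeCTD <- function(seq) {
  chars <- .seqChars(seq)
  L <- length(chars)
  .assert(L >= 2L, "CTD requires sequence length >= 2 (got %d)", L)
  idx <- match(chars, AA_ALPHABET)
  props <- names(CTD_GROUPS)
  comp <- trans <- numeric(0)
  dist <- numeric(0)
  landmarks <- c(0, 0.25, 0.5, 0.75, 1)
  for (pr in props) {
    g <- .ctdLookup[[pr]][idx]
    cnt <- tabulate(g, nbins = 3L)
    cblock <- cnt / L
    names(cblock) <- paste0("CTD.C.", pr, ".G", 1:3)
    comp <- c(comp, cblock)
    a <- g[-L]; b <- g[-1L]
    lo <- pmin(a, b); hi <- pmax(a, b)
    tblock <- c(sum(lo == 1 & hi == 2), sum(lo == 1 & hi == 3),
                sum(lo == 2 & hi == 3)) / (L - 1L)
    names(tblock) <- paste0("CTD.T.", pr, c(".G1G2", ".G1G3", ".G2G3"))
    trans <- c(trans, tblock)
    for (grp in 1:3) {
      pos <- which(g == grp)
      ng <- length(pos)
      if (ng == 0L) {
        dblock <- rep(0, 5L)
      } else {
        take <- pmax(1L, ceiling(landmarks * ng))
        dblock <- pos[take] / L * 100
      }
      names(dblock) <- paste0("CTD.D.", pr, ".G", grp, ".",
                              c("first", "p25", "p50", "p75", "p100"))
      dist <- c(dist, dblock)
    }
  }
  c(comp, trans, dist)
}

#' Conjoint-triad descriptor
#'
#' Residues are mapped to 7 conjoint classes and all 7^3 = 343 ordered
#' class triples of consecutive residues are scored `count / (L - 2)`,
#' so the vector sums to 1.
#'
#' @param seq sanitized amino-acid sequence, length >= 3.
#' @return named numeric vector of length 343.
#' @export
encodeCTriad <- function(seq) {
  chars <- .seqChars(seq)
  L <- length(chars)
  .assert(L >= 3L, "conjoint triad requires sequence length >= 3 (got %d)", L)
  cls <- .ctriadLookup[match(chars, AA_ALPHABET)]
  a <- cls[seq_len(L - 2L)]
  b <- cls[seq_len(L - 2L) + 1L]
  c3 <- cls[seq_len(L - 2L) + 2L]
  code <- (a - 1L) * 49L + (b - 1L) * 7L + c3
  counts <- tabulate(code, nbins = 343L)
  out <- counts / (L - 2L)
  grid <- expand.grid(k = 1:7, j = 1:7, i = 1:7)
  names(out) <- paste0("CTriad.", grid$i, ".", grid$j, ".", grid$k)
  out
}

#' Block layout of the full protein descriptor vector
#' @return named integer vector of block widths (AAC, CKSAAP, CTD, CTriad).
#' @export
featureBlockLayout <- function() {
  c(AAC = 20L, CKSAAP = 2400L, CTD = 273L, CTriad = 343L)
}

#' Encode one protein into the full 3036-dimensional descriptor vector
#'
#' Concatenates AAC | CKSAAP | CTD | CTriad (20 + 2400 + 273 + 343 = 3036).
#'
#' @param seq sanitized amino-acid sequence (must satisfy the strictest
#'   block precondition, length >= 7 for the default CKSAAP gaps).
#' @param id record identifier used in error messages.
#' @return numeric vector of length 3036 with a `block` attribute giving
#'   the layout.
#' @export
encodeProtein <- function(seq, id = "<sequence>") {
  out <- tryCatch(
    c(encodeAAC(seq), encodeCKSAAP(seq), encodeCTD(seq), encodeCTriad(seq)),
    error = function(e) {
      stop(sprintf("record %s: %s", id, conditionMessage(e)), call. = FALSE)
    })
  stopifnot(length(out) == 3036L, all(is.finite(out)))
  attr(out, "block") <- featureBlockLayout()
  out
}

#' Encode a set of proteins into a descriptor matrix
#'
#' @param seqs an [Biostrings::AAStringSet] or a named character vector of
#'   sanitized sequences.
#' @return numeric matrix (proteins x 3036) with sequence names as
#'   rownames.
#' @export
encodeProteins <- function(seqs) {
  if (methods::is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  .assert(length(seqs) >= 1L, "no sequences to encode")
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  X <- t(vapply(seq_along(seqs),
                function(i) as.numeric(encodeProtein(seqs[[i]], ids[i])),
                numeric(3036L)))
  rownames(X) <- ids
  colnames(X) <- names(encodeProtein(seqs[[1L]]))
  X
}

#' Fit a PCA model on protein descriptor vectors
#'
#' Fits PCA (by SVD, centred, unscaled) on the union of ligand and
#' receptor descriptor vectors so ligands and receptors share one latent
#' space.  The sign of each component is fixed so its largest-magnitude
#' loading is positive, making the fit deterministic.
#'
#' @param X numeric matrix, proteins x features.
#' @param d number of components to retain (default 200 so pair vectors
#'   have width 400).
#' @return a [ProteinPCA-class] object.
#' @export
fitProteinPCA <- function(X, d = 200L) {
  .assert(is.matrix(X) && nrow(X) >= 2L, "PCA requires at least 2 rows")
  d <- as.integer(d)
  .assert(length(d) == 1L && d >= 1L && d <= min(dim(X)),
          "d must be in [1, min(nrow, ncol)] = [1, %d]", min(dim(X)))
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = d)
  rot <- p$rotation[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  new("ProteinPCA", center = p$center, rotation = rot,
      sdev = p$sdev[seq_len(d)], d = d)
}

#' Project descriptor vectors through a fitted PCA model
#'
#' @param model a [ProteinPCA-class] object.
#' @param X numeric matrix or vector in the model's input space.
#' @return numeric matrix, rows projected to `d` dimensions.
#' @export
applyProteinPCA <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  .assert(ncol(X) == length(model@center),
          "input width %d does not match PCA input dimension %d",
          ncol(X), length(model@center))
  out <- sweep(X, 2L, model@center) %*% model@rotation
  rownames(out) <- rownames(X)
  out
}

#' Reconstruct descriptor vectors from their PCA projection
#' @param model a [ProteinPCA-class] object.
#' @param Z numeric matrix of projected rows (width `d`).
#' @return numeric matrix in the original input space.
#' @export
inverseProteinPCA <- function(model, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  sweep(Z %*% t(model@rotation), 2L, model@center, `+`)
}

#' Concatenate reduced ligand and receptor vectors into a pair vector
#'
#' Ligand block first, receptor block second; both must come from the
#' same PCA model so the result has width 2d.
#'
#' @param lvec,rvec numeric vectors of equal length d.
#' @return numeric vector of length 2d.
#' @examples
#' makePairVector(c(1, 2), c(3, 4))  # 1 2 3 4
#' @export
makePairVector <- function(lvec, rvec) {
  .assert(length(lvec) == length(rvec),
          "ligand and receptor vectors differ in length (%d vs %d)",
          length(lvec), length(rvec))
  c(as.numeric(lvec), as.numeric(rvec))
}

#' Build a PairFeatureSet from a pair table and reduced protein vectors
#'
#' @param pairs data.frame with columns `ligand_id`, `receptor_id` and
#'   optionally `label` (0/1; absent or `NA` = unlabeled).
#' @param reduced numeric matrix of PCA-reduced protein vectors with
#'   protein identifiers as rownames.
#' @return a [PairFeatureSet-class].
#' @export
buildPairFeatures <- function(pairs, reduced) {
  .assert(all(c("ligand_id", "receptor_id") %in% names(pairs)),
          "pair table needs ligand_id and receptor_id columns")
  missing <- setdiff(unique(c(pairs$ligand_id, pairs$receptor_id)),
                     rownames(reduced))
  .assert(length(missing) == 0L,
          "no reduced features for: %s", paste(missing, collapse = ", "))
  lv <- reduced[pairs$ligand_id, , drop = FALSE]
  rv <- reduced[pairs$receptor_id, , drop = FALSE]
  y <- if ("label" %in% names(pairs)) as.integer(pairs$label)
       else rep(NA_integer_, nrow(pairs))
  new("PairFeatureSet", ligandId = as.character(pairs$ligand_id),
      receptorId = as.character(pairs$receptor_id),
      x = unname(cbind(lv, rv)), y = y)
}
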