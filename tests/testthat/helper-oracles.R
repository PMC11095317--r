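# Independent brute-force oracles used to cross-check the vectorized
# implementations.  These deliberately use naive loops and no shared code
# paths with the package internals.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# gapped-pair enumeration: for each gap k walk every position pair
# (i, i + k + 1) and count, then divide by the number of such pairs
oracleCKSAAP <- function(seq, gaps = 0:5) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  out <- numeric(0)
  for (k in gaps) {
    counts <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
    for (i in seq_len(L - k - 1)) {
      counts[ch[i], ch[i + k + 1]] <- counts[ch[i], ch[i + k + 1]] + 1
    }
    out <- c(out, as.vector(t(counts)) / (L - k - 1))
  }
  out
}

# direct per-property computation of composition, transition and the five
# distribution landmarks
oracleCTD <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  groups <- stackCCC:::CTD_GROUPS
  comp <- trans <- dist <- numeric(0)
  for (pr in names(groups)) {
    g <- integer(L)
    for (gi in 1:3) {
      members <- strsplit(groups[[pr]][gi], "")[[1]]
      g[ch %in% members] <- gi
    }
    comp <- c(comp, sum(g == 1) / L, sum(g == 2) / L, sum(g == 3) / L)
    t12 <- t13 <- t23 <- 0
    for (i in seq_len(L - 1)) {
      pair <- sort(c(g[i], g[i + 1]))
      if (all(pair == c(1, 2))) t12 <- t12 + 1
      if (all(pair == c(1, 3))) t13 <- t13 + 1
      if (all(pair == c(2, 3))) t23 <- t23 + 1
    }
    trans <- c(trans, t12 / (L - 1), t13 / (L - 1), t23 / (L - 1))
    for (gi in 1:3) {
      pos <- which(g == gi)
      if (!length(pos)) {
        dist <- c(dist, rep(0, 5))
      } else {
        for (q in c(0, 0.25, 0.5, 0.75, 1)) {
          idx <- max(1, ceiling(q * length(pos)))
          dist <- c(dist, pos[idx] / L * 100)
        }
      }
    }
  }
  c(comp, trans, dist)
}

# enumerate every consecutive residue triple and bin by conjoint class
oracleCTriad <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  classes <- c("AGV", "ILFP", "YMTS", "HNQW", "RK", "DE", "C")
  cls <- integer(L)
  for (ci in seq_along(classes)) {
    cls[ch %in% strsplit(classes[ci], "")[[1]]] <- ci
  }
  counts <- array(0, c(7, 7, 7))
  for (i in seq_len(L - 2)) {
    counts[cls[i], cls[i + 1], cls[i + 2]] <-
      counts[cls[i], cls[i + 1], cls[i + 2]] + 1
  }
  # flatten with the third index fastest (first residue major)
  out <- numeric(343)
  pos <- 1
  for (a in 1:7) for (b in 1:7) for (c3 in 1:7) {
    out[pos] <- counts[a, b, c3]
    pos <- pos + 1
  }
  out / (L - 2)
}

# pairwise-ordering AUC: count correctly ordered positive/negative pairs,
# ties worth one half
oracleAuc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

randomSeq <- function(len) paste(sample(AA20, len, replace = TRUE),
                                 collapse = "")
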