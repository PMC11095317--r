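## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats var
.colVars <- function(X) {
  mu <- colMeans(X)
  colMeans(X^2) - mu^2
}

.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

## Deterministic per-stage seed fan-out from one root seed.  Kept below
## 2^31 - 1 so the result is always a valid R integer seed.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629L)
}

## Stratified index split: returns list(first, second) with `frac` of each
## class in `first`.  Sizes per class are rounded; the overall first part is
## frac of n within rounding.
stratifiedSplit <- function(y, frac, seed) {
  .assert(frac > 0 && frac < 1, "split fraction must be in (0, 1)")
  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(ii) {
      n1 <- round(length(ii) * frac)
      sample(ii, n1)
    }), use.names = FALSE)
  })
  list(first = sort(idx), second = sort(setdiff(seq_along(y), idx)))
}

.softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}
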