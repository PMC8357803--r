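# Internal helpers shared across modules.

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Derive a child RNG seed from a base seed and a counter
#'
#' Deterministic linear-congruential mixing keeps every source of randomness
#' traceable to one user-supplied seed while letting independent pipeline
#' stages (one per signature, permutation, or replicate) consume
#' non-overlapping streams. The result is always a valid 32-bit integer seed.
#'
#' @param seed single finite numeric base seed.
#' @param counter nonnegative integer stream index.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, counter = 0L) {
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "seed must be a single finite number")
  .assert(is.numeric(counter) && length(counter) == 1L && is.finite(counter),
          "counter must be a single finite number")
  as.integer((abs(as.double(seed)) * 69069 +
                abs(as.double(counter)) * 1013904223) %% 2147483629)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Column-wise cumulative sums without per-column apply overhead.
col_cumsum <- function(A) {
  k <- nrow(A)
  B <- ncol(A)
  if (k == 0L || B == 0L) return(A)
  cv <- matrix(cumsum(A), k, B)
  tot <- cv[k, ]
  cv - rep(c(0, tot[-B]), each = k)
}

# Column-wise max / min values of a matrix (value, not index).
col_max <- function(A) {
  A[cbind(max.col(t(A), ties.method = "first"), seq_len(ncol(A)))]
}
col_min <- function(A) {
  A[cbind(max.col(t(-A), ties.method = "first"), seq_len(ncol(A)))]
}
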