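# Shared helpers: seed handling, deterministic sub-seeds, stratified folds.

#' Derive a reproducible sub-seed from a base seed and index keys
#'
#' Folds `seed` and any number of integer keys through a Lehmer-style
#' congruential step modulo 2^31 - 1, so that per-replicate seeds depend only
#' on `(seed, keys)` and never on how many other replicates are run.
#'
#' @param seed base integer seed.
#' @param ... integer keys (e.g. bootstrap replicate index, fold index).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  x <- as.double(seed %% m)
  for (k in c(...)) {
    x <- (x * 48271 + as.double(k) * 16807 + 1) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

# Evaluate `expr` under `seed` and restore the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Outcome-stratified fold assignment: within each class, shuffled labels
# rep(1:v, length.out = n_class), so class balance per fold is as even as the
# counts allow.  Classes smaller than v are spread over distinct random
# folds; v = n degenerates to exact leave-one-out.  Returns an integer
# vector of fold ids aligned to `labels`.
stratified_folds <- function(labels, v, seed = NULL) {
  stopifnot(v >= 2)
  n <- length(labels)
  if (n < v) {
    stop("cannot build ", v, " folds from ", n, " rows", call. = FALSE)
  }
  with_seed(seed, {
    if (v == n) return(sample(seq_len(n)))
    fold <- integer(n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- if (length(idx) < v) {
        sample(v, length(idx))
      } else {
        sample(rep(seq_len(v), length.out = length(idx)))
      }
    }
    fold
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
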