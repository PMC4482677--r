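# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals do not
#' disturb user-level reproducibility.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive `n` sub-seeds from a master seed; each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Round to the nearest odd integer >= 3 (odd-length symmetric FIR kernels).
round_odd <- function(x) {
  k <- max(3, round(x))
  if (k %% 2 == 0) k + 1 else k
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Stratified split of indices: returns a list(train, val) with roughly
# `fraction` of each class in `val`, at least one element kept in train.
stratified_split <- function(y, fraction, seed) {
  idx <- seq_along(y)
  val <- with_seed(seed, {
    unlist(lapply(split(idx, y), function(ix) {
      n_val <- floor(length(ix) * fraction)
      if (n_val >= length(ix)) n_val <- length(ix) - 1L
      if (n_val <= 0) return(integer(0))
      sample(ix, n_val)
    }), use.names = FALSE)
  })
  list(train = setdiff(idx, val), val = sort(val))
}

# Stratified k-fold partition: list of k disjoint test index vectors that
# jointly cover seq_along(y).
stratified_folds <- function(y, k, seed) {
  folds <- vector("list", k)
  with_seed(seed, {
    for (ix in split(seq_along(y), y)) {
      ix <- sample(ix)
      fold_of <- rep_len(seq_len(k), length(ix))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], ix[fold_of == f])
      }
    }
  })
  lapply(folds, sort)
}
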