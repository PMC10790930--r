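#' @keywords internal
"_PACKAGE"

# Run expr under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All user-facing stochastic operations funnel through this so that
# (seed, params) -> identical output holds package-wide.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying inside
# the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1013 * as.numeric(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
}

# Stratified fold assignment: returns integer fold id per sample, balanced
# per class; used by the cross-validation harness and the inner grid search.
stratified_folds <- function(labels, k) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
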