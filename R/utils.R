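# Internal helpers shared across stages.

# Derive a reproducible stage seed from the master seed. Stage indices are
# small (< 100); the result stays well inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.integer(seed) %% 20000000L) * 100L + stage)
}

check_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` is required for every permutation stage (reproducibility).")
  }
  invisible(as.integer(seed))
}

# Floor p-values away from zero so -log10 stays finite; the floor matches the
# granularity of a B-permutation test.
floor_p <- function(p, B = 1000L) pmax(p, 1 / (B + 1))

# Row-standardize a genes x samples matrix; constant rows become NA rows.
zscore_rows <- function(X) {
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1L))
  (X - mu) / s
}

`%notin%` <- function(x, table) !(x %in% table)
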