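# Keep probabilities/rates strictly inside (0, 1) so log-odds stay finite.
clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Row-wise standardization statistics over observed entries. Constant rows
# get scale 1 (centering only) so downstream division is always defined.
row_standardize_stats <- function(values, mask = NULL, skip = NULL) {
  D <- nrow(values)
  if (is.null(mask)) mask <- !is.na(values)
  center <- numeric(D); scale <- rep(1, D)
  for (d in seq_len(D)) {
    x <- values[d, mask[d, ]]
    center[d] <- mean(x)
    s <- stats::sd(x)
    if (is.finite(s) && s > 0) scale[d] <- s
  }
  if (!is.null(skip) && any(skip)) {
    center[skip] <- 0
    scale[skip] <- 1
  }
  list(center = center, scale = scale)
}

apply_row_standardization <- function(values, stats) {
  (values - stats$center) / stats$scale
}

# log(1 + exp(x)) without overflow; used for Bernoulli log-odds -> prob.
sigmoid <- function(x) stats::plogis(x)

# Number of non-empty columns of a binary allocation matrix.
active_lc_count <- function(Z) sum(colSums(Z != 0) > 0)

# Derive a child seed (kept below 2^31) from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1000003 + stream * 7919) %% 2147483647)
}
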