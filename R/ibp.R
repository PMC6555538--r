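#' Sample from the finite-truncation Indian buffet process
#'
#' Draws per-column inclusion rates `v_k ~ Beta(alpha/k_max, 1)` and a binary
#' allocation matrix `Z_dk ~ Bernoulli(v_k)`. As `k_max` grows (with column
#' reordering) this finite construction converges to the Indian buffet
#' process, under which the expected number of non-empty columns is
#' `alpha * sum_{d=1}^{D} 1/d`. The finite, uncollapsed form is used
#' throughout because the Markov-random-field column prior needs an explicit
#' `v_k` per column.
#'
#' Uses the current R RNG stream; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param D number of rows (drugs).
#' @param hp hyperparameters, see [hyperparams()]; uses `alpha` and `k_max`.
#'
#' @return list with `v` (length `k_max`) and `Z` (`D x k_max` 0/1 matrix).
#' @export
sample_finite_ibp <- function(D, hp) {
  stopifnot(D >= 1, inherits(hp, "lc_hyperparams"))
  K <- hp$k_max
  v <- clamp01(stats::rbeta(K, hp$alpha / K, 1))
  Z <- matrix(as.numeric(stats::runif(D * K) < rep(v, each = D)), D, K)
  list(v = v, Z = Z)
}

#' Unnormalized MRF-modified log prior of one allocation column
#'
#' Evaluates `sum_{(d',d) in edges} w_{d'd} z_{d'} z_d +
#' sum_d [z_d log v_k + (1 - z_d) log(1 - v_k)]`: the usual independent
#' Bernoulli IBP column term plus pairwise Markov-random-field bonuses for
#' linked drugs using the same latent characteristic. The column-wise
#' partition function is never computed; only differences of this quantity
#' are used, which is all Gibbs sampling requires.
#'
#' @param z_col 0/1 vector of length `D`.
#' @param v_k inclusion rate in (0, 1).
#' @param graph optional [relation_graph()] over the `D` drugs.
#'
#' @return unnormalized log prior (a real number).
#' @export
mrf_column_log_prior <- function(z_col, v_k, graph = NULL) {
  if (v_k <= 0 || v_k >= 1) stop("v_k must lie strictly in (0, 1)")
  z_col <- as.numeric(z_col)
  stopifnot(all(z_col %in% c(0, 1)))
  lp <- sum(z_col * log(v_k) + (1 - z_col) * log1p(-v_k))
  if (!is.null(graph) && nrow(graph$edges) > 0) {
    if (graph$n_nodes != length(z_col))
      stop("graph node count != column length")
    e <- graph$edges
    lp <- lp + sum(e$weight * z_col[e$i] * z_col[e$j])
  }
  lp
}

#' Prior log-odds of a single allocation entry
#'
#' Log-odds of `Z[d,k] = 1` versus `0` conditional on the rest of column
#' `k`, its rate `v_k`, and the MRF graph:
#' `log(v_k / (1 - v_k)) + sum over neighbors d' of w_{d'd} Z[d',k]`.
#' This is the prior part of the Gibbs flip probability.
#'
#' @param d,k row (drug) and column (LC) indices.
#' @param state a latent state, see [init_state()].
#' @param graph optional [relation_graph()] over drugs.
#'
#' @return prior log-odds (a real number).
#' @export
prior_logodds_zdk <- function(d, k, state, graph = NULL) {
  stopifnot(d >= 1, d <= nrow(state$Z), k >= 1, k <= ncol(state$Z))
  v <- state$v[k]
  lo <- log(v) - log1p(-v)
  if (!is.null(graph) && nrow(graph$edges) > 0) {
    e <- graph$edges
    sel_i <- e$i == d
    sel_j <- e$j == d
    if (any(sel_i)) lo <- lo + sum(e$weight[sel_i] * state$Z[e$j[sel_i], k])
    if (any(sel_j)) lo <- lo + sum(e$weight[sel_j] * state$Z[e$i[sel_j], k])
  }
  lo
}
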