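#' Draw an initial latent state
#'
#' Draws a full model configuration: `v` and `pi` from their Beta priors,
#' `Z` and `V` from Bernoulli given the rates, loadings `G` and coefficients
#' `B` from the unit-variance slab where active (exactly zero elsewhere),
#' `X = B F` plus unit-variance noise, and all precisions (and their
#' hyperparameters `b_y`, `b_x`) at 1. An over-dispersed draw from the prior
#' is the natural starting point for Gibbs sampling.
#'
#' Uses the current R RNG stream.
#'
#' @param D,N,P numbers of drugs, cell lines and features.
#' @param hp hyperparameters, see [hyperparams()].
#' @param F_values optional `P x N` (standardized) feature values used for
#'   the `X = B F + noise` initialization; zero matrix if omitted.
#' @param precisions_from_prior if `TRUE`, draw `b_y`, `b_x` and the
#'   precision vectors from their Gamma priors instead of fixing them at 1
#'   (used for prior simulation and sampler validation).
#' @param support `"prior"` draws the binary supports `Z`, `V` (and slab
#'   coefficients) from the prior; `"empty"` starts them all-zero so that
#'   latent characteristics are born one at a time from evidence. The empty
#'   start is what [run_gibbs()] uses: with a prior-drawn start the chain
#'   tends to lock into states where one real LC is split across several
#'   initialized columns, which single-site flips are slow to merge.
#'
#' @return an object of class `latent_state` with fields `Z`, `G`, `v`, `X`,
#'   `V`, `B`, `pi`, `lam_y`, `b_y`, `lam_x`, `b_x`, `K`.
#' @export
init_state <- function(D, N, P, hp, F_values = NULL,
                       precisions_from_prior = FALSE,
                       support = c("prior", "empty")) {
  stopifnot(inherits(hp, "lc_hyperparams"))
  support <- match.arg(support)
  K <- hp$k_max
  beta <- resolve_beta(hp, P)
  if (support == "prior") {
    ibp <- sample_finite_ibp(D, hp)
    v <- ibp$v; Z <- ibp$Z
    G <- Z * matrix(stats::rnorm(D * K), D, K)
    pi <- clamp01(stats::rbeta(P, beta / P, 1))
    V <- matrix(as.numeric(stats::runif(K * P) < rep(pi, each = K)), K, P)
    B <- V * matrix(stats::rnorm(K * P), K, P)
  } else {
    v <- clamp01(stats::rbeta(K, hp$alpha / K, 1))
    Z <- matrix(0, D, K)
    G <- matrix(0, D, K)
    pi <- clamp01(stats::rbeta(P, beta / P, 1))
    V <- matrix(0, K, P)
    B <- matrix(0, K, P)
  }
  if (precisions_from_prior) {
    b_y <- stats::rgamma(1, 1, rate = 1)
    lam_y <- stats::rgamma(D, 1, rate = b_y)
    b_x <- stats::rgamma(1, 1, rate = 1)
    lam_x <- stats::rgamma(K, 1, rate = b_x)
  } else {
    b_y <- 1; lam_y <- rep(1, D)
    b_x <- 1; lam_x <- rep(1, K)
  }
  if (is.null(F_values)) F_values <- matrix(0, P, N)
  stopifnot(nrow(F_values) == P, ncol(F_values) == N)
  X <- B %*% F_values +
    matrix(stats::rnorm(K * N), K, N) / sqrt(lam_x)
  state <- list(Z = Z, G = G, v = v, X = X, V = V, B = B, pi = pi,
                lam_y = lam_y, b_y = b_y, lam_x = lam_x, b_x = b_x,
                K = K)
  class(state) <- "latent_state"
  state
}

#' Validate a latent state
#'
#' Checks the structural invariants: matching dimensions, exact zeros of `G`
#' (`B`) off the support of `Z` (`V`), rates strictly inside (0, 1),
#' strictly positive precisions, and finiteness.
#'
#' @param state a `latent_state`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_latent_state <- function(state) {
  with(state, {
    stopifnot(is.matrix(Z), is.matrix(G), is.matrix(X), is.matrix(V),
              is.matrix(B))
    D <- nrow(Z)
    stopifnot(ncol(Z) == K, all(dim(G) == c(D, K)),
              length(v) == K, nrow(X) == K,
              all(dim(V) == c(K, ncol(B))), nrow(B) == K,
              length(pi) == ncol(B), length(lam_y) == D,
              length(lam_x) == K)
    if (!all(Z %in% c(0, 1)) || !all(V %in% c(0, 1)))
      stop("Z and V must be binary")
    if (any(G[Z == 0] != 0)) stop("G must be exactly 0 where Z = 0")
    if (any(B[V == 0] != 0)) stop("B must be exactly 0 where V = 0")
    if (any(v <= 0 | v >= 1) || any(pi <= 0 | pi >= 1))
      stop("v and pi must lie strictly in (0, 1)")
    if (any(lam_y <= 0) || any(lam_x <= 0) || b_y <= 0 || b_x <= 0)
      stop("precisions and rate hyperparameters must be > 0")
    if (!all(is.finite(G)) || !all(is.finite(X)) || !all(is.finite(B)))
      stop("non-finite values in state")
  })
  invisible(TRUE)
}

# Forward-simulate sensitivity data given a state: Y = G X + eps, with
# per-drug noise precision lam_y. Returns the raw value matrix.
simulate_y_given_state <- function(state, N = ncol(state$X)) {
  D <- nrow(state$Z)
  state$G %*% state$X +
    matrix(stats::rnorm(D * N), D, N) / sqrt(state$lam_y)
}

# Re-draw X from its prior X = B F + noise(1/lam_x) (used by the
# joint-consistency sampler validation, where X counts as a parameter).
simulate_x_given_state <- function(state, F_values) {
  K <- state$K; N <- ncol(F_values)
  state$B %*% F_values +
    matrix(stats::rnorm(K * N), K, N) / sqrt(state$lam_x)
}
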