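#' Log joint density of the full model
#'
#' Sums the Gaussian log-likelihood of the observed sensitivity entries given
#' `G X` (per-drug precisions), the Gaussian log-density of the latent
#' characteristics `X` given `B F` (per-LC precisions), the spike-and-slab
#' priors on `G | Z` and `B | V`, the Beta priors on `v` and `pi`, the
#' Bernoulli priors of `Z | v` and `V | pi`, the hierarchical Gamma priors on
#' the precisions, and (when graphs are supplied) the pairwise
#' Markov-random-field terms `sum w Z Z` (and the feature analog). The MRF
#' contribution is unnormalized: its partition function is constant across
#' states for fixed graphs, so the value is valid for MCMC diagnostics and
#' within-chain comparisons.
#'
#' @param state a `latent_state`.
#' @param Y a [sensitivity_matrix()] (masked entries are skipped).
#' @param F a [feature_matrix()] with cell lines aligned to `Y`.
#' @param drug_graph,feat_graph optional [relation_graph()]s.
#'
#' @return unnormalized log joint density (a real number).
#' @export
log_joint <- function(state, Y, F, drug_graph = NULL, feat_graph = NULL) {
  Yv <- if (inherits(Y, "sensitivity_matrix")) Y$values else as.matrix(Y)
  mask <- if (inherits(Y, "sensitivity_matrix")) Y$observed_mask else !is.na(Yv)
  Fv <- if (inherits(F, "feature_matrix")) F$values else as.matrix(F)
  D <- nrow(Yv); N <- ncol(Yv); P <- nrow(Fv)
  K <- state$K
  if (nrow(state$Z) != D || ncol(state$X) != N || ncol(state$B) != P ||
      ncol(Fv) != N)
    stop("state dimensions inconsistent with Y / F")
  if (!all(is.finite(state$G)) || !all(is.finite(state$X)) ||
      !all(is.finite(state$B)))
    stop("non-finite values in state")

  hp <- attr(state, "hp")
  alpha_over_K <- if (is.null(hp)) 1 else hp$alpha / hp$k_max
  beta_over_P <- if (is.null(hp)) 1 else resolve_beta(hp, P) / P

  mu_y <- state$G %*% state$X
  res_y <- (Yv - mu_y)
  res_y[!mask] <- 0
  n_d <- rowSums(mask)
  ll_y <- sum(0.5 * n_d * (log(state$lam_y) - log(2 * pi))) -
    0.5 * sum(state$lam_y * rowSums(res_y^2))

  res_x <- state$X - state$B %*% Fv
  ll_x <- sum(0.5 * N * (log(state$lam_x) - log(2 * pi))) -
    0.5 * sum(state$lam_x * rowSums(res_x^2))

  lp_g <- sum(stats::dnorm(state$G[state$Z == 1], 0, 1, log = TRUE))
  lp_b <- sum(stats::dnorm(state$B[state$V == 1], 0, 1, log = TRUE))

  lp_z <- sum(sweep(state$Z, 2, log(state$v), "*") +
                sweep(1 - state$Z, 2, log1p(-state$v), "*"))
  lp_vmat <- sum(sweep(state$V, 2, log(state$pi), "*") +
                   sweep(1 - state$V, 2, log1p(-state$pi), "*"))

  lp_mrf <- 0
  if (!is.null(drug_graph) && nrow(drug_graph$edges) > 0) {
    e <- drug_graph$edges
    lp_mrf <- lp_mrf + sum(e$weight *
      rowSums(state$Z[e$i, , drop = FALSE] * state$Z[e$j, , drop = FALSE]))
  }
  if (!is.null(feat_graph) && nrow(feat_graph$edges) > 0) {
    e <- feat_graph$edges
    lp_mrf <- lp_mrf + sum(e$weight *
      colSums(state$V[, e$i, drop = FALSE] * state$V[, e$j, drop = FALSE]))
  }

  lp_v <- sum(stats::dbeta(state$v, alpha_over_K, 1, log = TRUE))
  lp_pi <- sum(stats::dbeta(state$pi, beta_over_P, 1, log = TRUE))

  lp_noise <- sum(stats::dgamma(state$lam_y, 1, rate = state$b_y, log = TRUE)) +
    stats::dgamma(state$b_y, 1, rate = 1, log = TRUE) +
    sum(stats::dgamma(state$lam_x, 1, rate = state$b_x, log = TRUE)) +
    stats::dgamma(state$b_x, 1, rate = 1, log = TRUE)

  ll_y + ll_x + lp_g + lp_b + lp_z + lp_vmat + lp_mrf + lp_v + lp_pi + lp_noise
}

# Trace container. Standardization statistics default to the identity
# transform so manually built traces predict on the raw scale.
posterior_trace <- function(states, log_joint, config_echo,
                            drug_ids = NULL, cell_ids = NULL,
                            feature_ids = NULL, standardization = NULL) {
  stopifnot(length(states) == length(log_joint), length(states) >= 1)
  structure(list(states = states, log_joint = as.numeric(log_joint),
                 config_echo = config_echo, drug_ids = drug_ids,
                 cell_ids = cell_ids, feature_ids = feature_ids,
                 standardization = standardization),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  counts <- vapply(x$states, function(s) active_lc_count(s$Z), numeric(1))
  cat(sprintf(paste0("posterior_trace: %d states, active LCs %d-%d ",
                     "(mode %d), final log-joint %.2f\n"),
              length(x$states), min(counts), max(counts),
              posterior_mode_count(counts), x$log_joint[length(x$log_joint)]))
  invisible(x)
}

posterior_mode_count <- function(counts) {
  tab <- table(counts)
  as.integer(names(tab)[which.max(tab)])
}

#' Posterior-mode number of active latent characteristics
#'
#' @param trace a `posterior_trace`.
#' @return the most frequent count of non-empty LCs across recorded states.
#' @export
active_lc_mode <- function(trace) {
  posterior_mode_count(vapply(trace$states,
                              function(s) active_lc_count(s$Z), numeric(1)))
}

#' The recorded state with the highest log joint density
#'
#' Used to summarize a trace for interpretation (association tables), where
#' averaging across sweeps is not meaningful because LC labels are arbitrary.
#'
#' @param trace a `posterior_trace`.
#' @return a `latent_state`.
#' @export
trace_best_state <- function(trace) {
  trace$states[[which.max(trace$log_joint)]]
}

#' Posterior mean prediction for new cell lines
#'
#' Averages `G B F_new` over the recorded posterior states. If the trace
#' carries training standardization statistics (the default when fitted via
#' [run_gibbs()]), `F_new`'s continuous rows are standardized with the
#' training means/SDs and predictions are returned on the original
#' sensitivity scale.
#'
#' @param trace a `posterior_trace`.
#' @param F_new a [feature_matrix()] with the same features (by id, in
#'   order) as the training data, over any number of cell lines.
#'
#' @return `D x M` matrix of predicted sensitivities (drugs x new cells).
#' @export
predict_mean <- function(trace, F_new) {
  Fv <- if (inherits(F_new, "feature_matrix")) F_new$values else as.matrix(F_new)
  if (!is.null(trace$feature_ids)) {
    ids <- if (inherits(F_new, "feature_matrix")) F_new$feature_ids else rownames(Fv)
    if (!identical(as.character(ids), as.character(trace$feature_ids)))
      stop("feature ids of F_new do not match the training features")
  }
  st <- trace$standardization
  if (!is.null(st)) Fv <- (Fv - st$f_center) / st$f_scale
  acc <- 0
  for (s in trace$states) acc <- acc + s$G %*% (s$B %*% Fv)
  pred <- acc / length(trace$states)
  if (!is.null(st)) pred <- pred * st$y_scale + st$y_center
  rownames(pred) <- trace$drug_ids
  if (inherits(F_new, "feature_matrix")) colnames(pred) <- F_new$cell_ids
  pred
}
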