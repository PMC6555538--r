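# Shared builders for small model states and datasets.

# Minimal hand-built latent state with hyperparameters attached.
tiny_state <- function(D = 1, N = 1, P = 1, K = 1,
                       alpha = 1, beta = 1, k_max = K) {
  hp <- hyperparams(alpha = alpha, beta = beta, k_max = k_max)
  st <- list(Z = matrix(0, D, K), G = matrix(0, D, K),
             v = rep(0.5, K), X = matrix(0, K, N),
             V = matrix(0, K, P), B = matrix(0, K, P),
             pi = rep(0.5, P), lam_y = rep(1, D), b_y = 1,
             lam_x = rep(1, K), b_x = 1, K = K)
  class(st) <- "latent_state"
  attr(st, "hp") <- hp
  st
}

tiny_Y <- function(values) sensitivity_matrix(as.matrix(values))
tiny_F <- function(values) feature_matrix(as.matrix(values))

# Quadrature oracle for one spike-and-slab site: posterior inclusion
# probability and slab posterior mean/sd by numerical integration (dense
# grid; robust to sharply peaked likelihoods) of the unit-slab marginal
# against Gaussian observations.
quad_spike_slab <- function(prior_logodds, prec, x, r,
                            grid = seq(-10, 10, length.out = 2000001)) {
  loglik <- function(g) {
    out <- numeric(length(g))
    for (n in seq_along(r))
      out <- out + stats::dnorm(r[n], g * x[n], 1 / sqrt(prec), log = TRUE)
    out
  }
  lp1 <- stats::dnorm(grid, log = TRUE) + loglik(grid)
  h <- grid[2] - grid[1]
  mx <- max(lp1)
  w <- exp(lp1 - mx)
  m1_log <- mx + log(sum(w) * h)
  m0_log <- loglik(0)
  log_bf <- m1_log - m0_log
  p1 <- stats::plogis(prior_logodds + log_bf)
  wn <- w / sum(w)
  pm <- sum(wn * grid)
  pv <- sum(wn * grid^2) - pm^2
  list(p1 = p1, mean = pm, sd = sqrt(pv))
}

# Cache for the parameter-recovery experiment shared by several acceptance
# checks (computed once per session).
.recovery_cache <- new.env(parent = emptyenv())

recovery_cfg <- function(seed) {
  gibbs_config(n_iter = 2000, burn_in = 1000, thin = 10, seed = seed,
               hp = hyperparams(alpha = 2, k_max = 10))
}

recovery_runs <- function() {
  if (!is.null(.recovery_cache$res)) return(.recovery_cache$res)
  seeds <- 1:10
  res <- lapply(seeds, function(s) {
    sim <- simulate_lc_data(sim_config(seed = s))
    tr_plain <- run_gibbs(sim$Y, sim$F, recovery_cfg(1000 + s))
    tr_graph <- run_gibbs(sim$Y, sim$F, recovery_cfg(1000 + s),
                          drug_graph = sim$drug_graph)
    list(sim = sim,
         mode_plain = active_lc_mode(tr_plain),
         f1_plain = support_f1(trace_best_state(tr_plain)$Z, sim$truth$Z),
         mode_graph = active_lc_mode(tr_graph),
         f1_graph = support_f1(trace_best_state(tr_graph)$Z, sim$truth$Z))
  })
  .recovery_cache$res <- res
  res
}
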