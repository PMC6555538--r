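# Joint-consistency ("getting it right") check: a successive-conditional
# sampler that alternates one Gibbs sweep with re-simulation of the data has
# the prior as its stationary distribution over parameters, so moments of
# parameter functionals must match plain forward draws from the prior.
# Compared functionals: mean Z fill, mean v, mean pi, mean log(lam_y) (the
# log keeps the heavy-tailed precision functional integrable).

geweke_statistics <- function(state) {
  c(z_fill = mean(state$Z), v = mean(state$v), pi = mean(state$pi),
    log_lam_y = mean(log(state$lam_y)))
}

geweke_experiment <- function(n_sweeps = 20000, burn = 2000,
                              n_forward = 20000, seed = 123) {
  D <- 4; N <- 6; P <- 3
  hp <- hyperparams(alpha = 1, beta = 1, k_max = 3)
  set.seed(seed)
  Fv <- matrix(stats::rnorm(P * N), P, N)
  mask <- matrix(TRUE, D, N)

  state <- init_state(D, N, P, hp, F_values = Fv,
                      precisions_from_prior = TRUE)
  attr(state, "hp") <- hp
  Yv <- lcsens:::simulate_y_given_state(state)
  dat <- lcsens:::make_sweep_data(Yv, mask, Fv, hp)
  succ <- matrix(NA_real_, n_sweeps, 4)
  for (i in seq_len(n_sweeps)) {
    dat$Y0 <- Yv
    state <- lcsens:::gibbs_sweep(state, dat)
    Yv <- lcsens:::simulate_y_given_state(state)
    succ[i, ] <- geweke_statistics(state)
  }
  succ <- succ[(burn + 1):n_sweeps, , drop = FALSE]

  fwd <- matrix(NA_real_, n_forward, 4)
  for (i in seq_len(n_forward)) {
    st <- init_state(D, N, P, hp, F_values = Fv,
                     precisions_from_prior = TRUE)
    fwd[i, ] <- geweke_statistics(st)
  }
  colnames(succ) <- colnames(fwd) <- names(geweke_statistics(state))
  list(succ = succ, fwd = fwd)
}

# Batch-means standard error for an autocorrelated sequence.
batch_se <- function(x, n_batch = 100) {
  m <- length(x) %/% n_batch
  bm <- vapply(seq_len(n_batch), function(b)
    mean(x[((b - 1) * m + 1):(b * m)]), numeric(1))
  stats::sd(bm) / sqrt(n_batch)
}
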