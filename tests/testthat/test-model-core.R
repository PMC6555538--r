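test_that("log joint equals the term-by-term sum on a minimal state", {
  st <- tiny_state(D = 1, N = 1, P = 1, K = 1, alpha = 1, beta = 1)
  Y <- tiny_Y(0); F <- tiny_F(0)
  # independent summation: Gaussian likelihoods of y and x, Bernoulli terms
  # for the empty supports, flat Beta(1,1) rate priors, Exp(1) noise terms
  expected <- stats::dnorm(0, 0, 1, log = TRUE) +            # y | Gx = 0
    stats::dnorm(0, 0, 1, log = TRUE) +                      # x | BF = 0
    log(1 - 0.5) +                                           # Z = 0 | v
    log(1 - 0.5) +                                           # V = 0 | pi
    stats::dbeta(0.5, 1, 1, log = TRUE) * 2 +                # v, pi
    stats::dgamma(1, 1, rate = 1, log = TRUE) * 4            # lam_y, b_y, lam_x, b_x
  expect_equal(log_joint(st, Y, F), expected, tolerance = 1e-12)
  expect_true(is.finite(log_joint(st, Y, F)))
})

test_that("log joint responds to single-scalar changes by the local delta", {
  set.seed(10)
  D <- 4; N <- 6; P <- 3; K <- 2
  st <- tiny_state(D = D, N = N, P = P, K = K)
  st$Z[] <- rbinom(D * K, 1, 0.6)
  st$G <- st$Z * matrix(rnorm(D * K), D, K)
  st$V[] <- rbinom(K * P, 1, 0.6)
  st$B <- st$V * matrix(rnorm(K * P), K, P)
  st$X <- matrix(rnorm(K * N), K, N)
  st$lam_y <- runif(D, 0.5, 2); st$lam_x <- runif(K, 0.5, 2)
  Yv <- matrix(rnorm(D * N), D, N); Yv[2, 3] <- NA
  Y <- tiny_Y(Yv); F <- tiny_F(matrix(rnorm(P * N), P, N))

  lj0 <- log_joint(st, Y, F)

  # perturb one active loading: only drug d's observed likelihood row and
  # its slab prior term change
  d <- which(rowSums(st$Z) > 0)[1]; k <- which(st$Z[d, ] == 1)[1]
  st2 <- st; st2$G[d, k] <- st$G[d, k] + 0.37
  obs <- Y$observed_mask[d, ]
  row_ll <- function(s) sum(stats::dnorm(Yv[d, obs],
                                         (s$G %*% s$X)[d, obs],
                                         1 / sqrt(s$lam_y[d]), log = TRUE))
  delta <- (row_ll(st2) - row_ll(st)) +
    stats::dnorm(st2$G[d, k], log = TRUE) - stats::dnorm(st$G[d, k], log = TRUE)
  expect_equal(log_joint(st2, Y, F) - lj0, delta, tolerance = 1e-8)

  # perturb one latent value: one y column and one x entry change
  n <- 2; kk <- 1
  st3 <- st; st3$X[kk, n] <- st$X[kk, n] - 0.53
  obs_n <- Y$observed_mask[, n]
  col_ll <- function(s) {
    mu <- (s$G %*% s$X)[, n]
    sum(stats::dnorm(Yv[obs_n, n], mu[obs_n],
                     1 / sqrt(s$lam_y[obs_n]), log = TRUE)) +
      stats::dnorm(s$X[kk, n], (s$B %*% F$values)[kk, n],
                   1 / sqrt(s$lam_x[kk]), log = TRUE)
  }
  expect_equal(log_joint(st3, Y, F) - lj0, col_ll(st3) - col_ll(st),
               tolerance = 1e-8)
})

test_that("zero-weight or absent graphs leave the log joint unchanged", {
  set.seed(11)
  st <- tiny_state(D = 3, N = 4, P = 2, K = 2)
  st$Z[] <- rbinom(6, 1, 0.5); st$G <- st$Z * matrix(rnorm(6), 3, 2)
  Y <- tiny_Y(matrix(rnorm(12), 3, 4)); F <- tiny_F(matrix(rnorm(8), 2, 4))
  g0 <- relation_graph(3, data.frame(i = c(1, 1), j = c(2, 3),
                                     weight = c(0, 0)))
  f0 <- relation_graph(2, data.frame(i = 1, j = 2, weight = 0))
  expect_identical(log_joint(st, Y, F, g0, f0), log_joint(st, Y, F))
  # a positive weight changes it iff linked drugs co-load
  g1 <- relation_graph(3, data.frame(i = 1, j = 2, weight = 2))
  shared <- sum(2 * st$Z[1, ] * st$Z[2, ])
  expect_equal(log_joint(st, Y, F, g1) - log_joint(st, Y, F), shared)
})

test_that("the generating state scores higher than perturbed states", {
  sim <- simulate_lc_data(sim_config(D = 6, N = 80, P = 10, K_true = 2,
                                     drugs_per_lc = 3, features_per_lc = 3,
                                     seed = 5))
  truth <- sim$truth
  attr(truth, "hp") <- hyperparams(alpha = 1, beta = 1, k_max = truth$K)
  lj_true <- log_joint(truth, sim$Y, sim$F)
  set.seed(6)
  lj_pert <- replicate(100, {
    p <- truth
    p$G <- p$G + p$Z * matrix(rnorm(length(p$G), sd = 0.5), nrow(p$G))
    log_joint(p, sim$Y, sim$F)
  })
  expect_gt(lj_true, mean(lj_pert))
})

test_that("posterior mean prediction averages G B F over states", {
  mk_state <- function(G, B) {
    st <- tiny_state(D = nrow(G), N = 1, P = ncol(B), K = ncol(G))
    st$Z <- (G != 0) * 1; st$G <- G
    st$V <- (B != 0) * 1; st$B <- B
    st
  }
  cfg <- gibbs_config(n_iter = 2, burn_in = 1, thin = 1)
  # single zero state
  tr <- lcsens:::posterior_trace(list(mk_state(matrix(0, 2, 1),
                                               matrix(0, 1, 2))), 0, cfg)
  expect_equal(predict_mean(tr, matrix(rnorm(6), 2, 3)), matrix(0, 2, 3),
               ignore_attr = TRUE)
  # two states with opposite products cancel
  G <- matrix(c(1, 2), 2, 1); B <- matrix(c(3, -1), 1, 2)
  tr2 <- lcsens:::posterior_trace(list(mk_state(G, B), mk_state(-G, B)),
                                  c(0, 0), cfg)
  expect_equal(predict_mean(tr2, matrix(rnorm(6), 2, 3)), matrix(0, 2, 3),
               ignore_attr = TRUE, tolerance = 1e-12)
  # scalar arithmetic
  tr3 <- lcsens:::posterior_trace(list(mk_state(matrix(2, 1, 1),
                                               matrix(3, 1, 1))), 0, cfg)
  expect_equal(predict_mean(tr3, matrix(c(1, -1), 1, 2)),
               matrix(c(6, -6), 1, 2), ignore_attr = TRUE)
  # linearity in F_new
  tr4 <- lcsens:::posterior_trace(list(mk_state(G, B), mk_state(2 * G, -B)),
                                  c(0, 0), cfg)
  F1 <- matrix(rnorm(4), 2, 2); F2 <- matrix(rnorm(4), 2, 2)
  expect_equal(predict_mean(tr4, 2 * F1 - 3 * F2),
               2 * predict_mean(tr4, F1) - 3 * predict_mean(tr4, F2),
               tolerance = 1e-12)
})
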