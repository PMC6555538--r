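test_that("latent update reduces to the prior when loadings are zero", {
  set.seed(20)
  K <- 2; N <- 5; P <- 3; D <- 4
  st <- tiny_state(D = D, N = N, P = P, K = K)
  st$B[] <- rnorm(K * P); st$V[] <- 1
  st$lam_x <- c(0.5, 4)
  Y <- tiny_Y(matrix(rnorm(D * N), D, N))
  F <- tiny_F(matrix(rnorm(P * N), P, N))
  set.seed(77)
  out <- update_latent(st, Y, F)
  set.seed(77)
  z <- matrix(rnorm(K * N), K, N)
  expect_equal(out$X, unname(st$B %*% F$values) + z / sqrt(st$lam_x),
               tolerance = 1e-12)
})

test_that("loadings flip at the prior rate when the LC row is uninformative", {
  set.seed(21)
  D <- 400
  st <- tiny_state(D = D, N = 10, P = 1, K = 1)
  st$X[] <- 0                      # zero LC row: Bayes factor is 1
  Y <- tiny_Y(matrix(rnorm(D * 10), D, 10))
  out <- update_loadings(st, Y)
  phat <- mean(out$Z)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / D))
})

test_that("loadings switch on under overwhelming evidence", {
  set.seed(22)
  st <- tiny_state(D = 1, N = 20, P = 1, K = 1)
  st$lam_y <- 100
  st$X[1, ] <- rnorm(20)
  Y <- tiny_Y(matrix(5 * st$X[1, ], 1))   # residual exactly 5 * x
  out <- update_loadings(st, Y)
  expect_equal(out$Z[1, 1], 1)
  expect_gt(out$G[1, 1], 0)
  # the analytic flip probability at these values exceeds 0.999
  q <- 1 + 100 * sum(st$X^2); s <- 100 * sum(5 * st$X^2)
  expect_gt(stats::plogis(-0.5 * log(q) + 0.5 * s^2 / q), 0.999)
})

test_that("feature inclusion is prior-dominated when pi approaches 1", {
  st <- tiny_state(D = 2, N = 4, P = 2, K = 3)
  st$pi <- rep(1 - 1e-9, 2)
  F <- tiny_F(matrix(0, 2, 4))            # zero features: likelihood flat
  set.seed(23)
  out <- update_regression(st, F)
  expect_true(all(out$V == 1))
})

test_that("sparsity rates are conjugate Beta draws with the right moments", {
  st <- tiny_state(D = 3, N = 2, P = 2, K = 1, alpha = 1, k_max = 1)
  st$Z[] <- 1                             # m_k = 3, alpha/K = 1 -> Beta(4, 1)
  set.seed(24)
  vs <- replicate(2000, update_sparsity(st)$v)
  se <- sqrt(4 / (25 * 6)) / sqrt(2000)
  expect_lt(abs(mean(vs) - 0.8), 3 * se)

  # empty matrix bookkeeping: v ~ Beta(alpha/K, 1 + D), checked draw-for-draw
  st0 <- tiny_state(D = 3, N = 2, P = 2, K = 2, alpha = 1, k_max = 2)
  set.seed(25)
  out <- update_sparsity(st0)
  set.seed(25)
  v_ref <- lcsens:::clamp01(rbeta(2, 0.5, 1 + 3))
  pi_ref <- lcsens:::clamp01(rbeta(2, 0.5, 1 + 2))
  expect_identical(out$v, v_ref)
  expect_identical(out$pi, pi_ref)
})

test_that("noise precisions follow their conjugate Gamma conditionals", {
  # D = 1, residual sum of squares 2 over 4 entries, b_y = 1 -> Gamma(3, 2)
  st <- tiny_state(D = 1, N = 4, P = 1, K = 1)
  Yv <- matrix(sqrt(0.5), 1, 4)           # rss = 4 * 0.5 = 2 with GX = 0
  Y <- tiny_Y(Yv); F <- tiny_F(matrix(0, 1, 4))
  set.seed(26)
  lam <- replicate(3000, update_noise(st, Y, F)$lam_y)
  se <- sqrt(3 / 4) / sqrt(3000)          # Gamma(3, 2): mean 1.5, var 3/4
  expect_lt(abs(mean(lam) - 1.5), 3 * se)

  # fully masked row falls back to the prior Gamma(1, b_y)
  Y0 <- matrix(0, 2, 3); M0 <- matrix(c(0, 1), 2, 3)
  st2 <- tiny_state(D = 2, N = 3, P = 1, K = 1)
  st2$b_y <- 2.5
  set.seed(27)
  out <- lcsens:::upd_noise_core(st2, Y0, M0, matrix(0, 1, 3),
                                 n_d = rowSums(M0), all_obs = FALSE)
  set.seed(27)
  lam_ref <- rgamma(2, 1 + c(0, 3) / 2, rate = 2.5)
  expect_identical(out$lam_y, lam_ref)
})

test_that("the trace records the configured post-burn-in snapshots", {
  sim <- simulate_lc_data(sim_config(D = 4, N = 20, P = 5, K_true = 2,
                                     drugs_per_lc = 2, features_per_lc = 2,
                                     seed = 9))
  cfg1 <- gibbs_config(n_iter = 11, burn_in = 10, thin = 1, seed = 2,
                       hp = hyperparams(k_max = 5))
  tr1 <- run_gibbs(sim$Y, sim$F, cfg1)
  expect_length(tr1$states, 1)
  expect_length(tr1$log_joint, 1)

  cfg2 <- gibbs_config(n_iter = 30, burn_in = 10, thin = 5, seed = 2,
                       hp = hyperparams(k_max = 5))
  tr2 <- run_gibbs(sim$Y, sim$F, cfg2)
  expect_length(tr2$states, 4)
  for (s in tr2$states) expect_silent(validate_latent_state(s))
})

test_that("identical seeds and inputs give bit-identical traces", {
  sim <- simulate_lc_data(sim_config(D = 5, N = 25, P = 6, K_true = 2,
                                     drugs_per_lc = 2, features_per_lc = 2,
                                     seed = 8))
  cfg <- gibbs_config(n_iter = 40, burn_in = 20, thin = 4, seed = 13,
                      hp = hyperparams(k_max = 4))
  tr_a <- run_gibbs(sim$Y, sim$F, cfg)
  tr_b <- run_gibbs(sim$Y, sim$F, cfg)
  expect_identical(tr_a$states, tr_b$states)
  expect_identical(tr_a$log_joint, tr_b$log_joint)
})

test_that("the fit warns when the truncation level is saturated", {
  sim <- simulate_lc_data(sim_config(D = 4, N = 30, P = 5, K_true = 2,
                                     drugs_per_lc = 2, features_per_lc = 2,
                                     seed = 14))
  cfg <- gibbs_config(n_iter = 30, burn_in = 20, thin = 2, seed = 3,
                      hp = hyperparams(k_max = 1))
  expect_warning(run_gibbs(sim$Y, sim$F, cfg), "k_max")
})
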