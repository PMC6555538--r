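test_that("pooled PVE identities and affine invariance hold", {
  y <- matrix(c(1, 2, 3), 1)
  expect_equal(pve(y, y, train_row_means = 2), 1)
  expect_equal(pve(y, matrix(2, 1, 3), train_row_means = 2), 0)
  expect_equal(pve(y, matrix(c(1, 2, 4), 1), train_row_means = 2), 0.5)

  set.seed(30)
  yo <- matrix(rnorm(20), 4); yp <- matrix(rnorm(20), 4)
  tm <- rnorm(4)
  a <- 3.7; b <- -1.2
  expect_equal(pve(a * yo + b, a * yp + b, a * tm + b), pve(yo, yp, tm),
               tolerance = 1e-12)
  expect_error(pve(matrix(2, 1, 3), matrix(1, 1, 3), train_row_means = 2),
               "SS_tot")
})

test_that("concordance index scores pair orderings as expected", {
  expect_equal(concordance_index(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(concordance_index(c(1, 2, 3), c(30, 20, 10)), 0)
  expect_equal(concordance_index(c(1, 2, 3), c(2, 1, 3)), 2 / 3)
  expect_equal(concordance_index(c(1, 2, 3), c(5, 5, 5)), 0.5) # all tied preds
  expect_error(concordance_index(c(2, 2), c(1, 3)), "tied")

  set.seed(31)
  y <- rnorm(25)
  expect_equal(concordance_index(y, y), 1)
  expect_equal(concordance_index(y, -y), 0)
  cis <- replicate(400, concordance_index(y, rnorm(25)))
  se <- stats::sd(cis) / sqrt(length(cis))
  expect_lt(abs(mean(cis) - 0.5), 3 * se)
})

test_that("Spearman rho and p agree with exact permutation enumeration", {
  x <- 1:6
  expect_equal(spearman_rho_p(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman_rho_p(x, -x)$rho, -1)

  all_perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  all_perms <- all_perms[apply(all_perms, 1, function(r)
    length(unique(r)) == 6), , drop = FALSE]
  set.seed(32)
  for (rep in 1:3) {
    xs <- rnorm(6); ys <- rnorm(6)
    got <- spearman_rho_p(xs, ys)
    expect_equal(got$rho, stats::cor(xs, ys, method = "spearman"))
    rhos <- apply(all_perms, 1, function(pm)
      stats::cor(rank(xs), rank(ys[pm])))
    # exact null is discrete with sizable atoms at M = 6: compare against
    # the mid-p (half weight on the observed atom), the standard
    # continuity-respecting reference for a continuous approximation
    p_mid <- mean(abs(rhos) > abs(got$rho) + 1e-12) +
      0.5 * mean(abs(abs(rhos) - abs(got$rho)) <= 1e-12)
    expect_lt(abs(got$p - p_mid), 0.02)
  }
  expect_error(spearman_rho_p(rep(1, 5), rnorm(5)), "rank variance")
})

test_that("cross-validation partitions cells and is seed-reproducible", {
  sim <- simulate_lc_data(sim_config(D = 5, N = 33, P = 6, K_true = 2,
                                     drugs_per_lc = 2, features_per_lc = 2,
                                     seed = 33))
  cfg <- gibbs_config(n_iter = 60, burn_in = 30, thin = 5, seed = 4,
                      hp = hyperparams(k_max = 6))
  res <- cross_validate(sim$Y, sim$F, cfg, n_folds = 5)
  held <- unlist(lapply(res, `[[`, "held_out_cell_ids"))
  expect_setequal(held, sim$Y$cell_ids)
  expect_length(held, 33)
  sizes <- lengths(lapply(res, `[[`, "held_out_cell_ids"))
  expect_lte(diff(range(sizes)), 1)
  for (r in res) expect_true(all(r$per_drug_cindex >= 0 &
                                   r$per_drug_cindex <= 1, na.rm = TRUE))

  res2 <- cross_validate(sim$Y, sim$F, cfg, n_folds = 5)
  expect_identical(vapply(res, `[[`, numeric(1), "pve"),
                   vapply(res2, `[[`, numeric(1), "pve"))
})

test_that("training standardization never uses held-out columns", {
  sim <- simulate_lc_data(sim_config(D = 4, N = 24, P = 5, K_true = 2,
                                     drugs_per_lc = 2, features_per_lc = 2,
                                     seed = 34))
  train_idx <- 1:16
  Ytr <- lcsens:::subset_cells(sim$Y, train_idx)
  Ftr <- lcsens:::subset_cells(sim$F, train_idx)
  cfg <- gibbs_config(n_iter = 10, burn_in = 5, thin = 1, seed = 1,
                      hp = hyperparams(k_max = 3))
  tr <- run_gibbs(Ytr, Ftr, cfg)
  expect_equal(tr$standardization$y_center, unname(rowMeans(Ytr$values)))
  expect_equal(tr$standardization$y_scale,
               unname(apply(Ytr$values, 1, sd)))
  # mutation rows are never rescaled
  mut <- sim$F$kind_of == "mutation"
  expect_true(all(tr$standardization$f_center[mut] == 0))
  expect_true(all(tr$standardization$f_scale[mut] == 1))
})

test_that("association tables enumerate active LC drug-feature pairs", {
  cfg <- gibbs_config(n_iter = 2, burn_in = 1, thin = 1)
  st <- tiny_state(D = 3, N = 10, P = 4, K = 2)
  set.seed(35)
  Y <- tiny_Y(matrix(rnorm(30), 3, 10))
  F <- tiny_F(matrix(rnorm(40), 4, 10))
  tr <- lcsens:::posterior_trace(list(st), 0, cfg, drug_ids = Y$drug_ids,
                                 feature_ids = F$feature_ids)
  expect_equal(nrow(lc_association_table(tr, Y, F)), 0)

  st$Z[c(1, 3), 1] <- 1
  st$V[1, 1:3] <- 1
  tr2 <- lcsens:::posterior_trace(list(st), 0, cfg, drug_ids = Y$drug_ids,
                                  feature_ids = F$feature_ids)
  tab <- lc_association_table(tr2, Y, F, bh_adjust = TRUE)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$lc_id == 1))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  expect_true(all(tab$p_adj >= tab$p - 1e-12))

  # positive-chain sign propagation: feature drives LC drives drug
  f <- rnorm(10)
  fv <- rbind(f, matrix(rnorm(30), 3, 10)); rownames(fv) <- NULL
  yv <- rbind(2 * f + rnorm(10, sd = 0.1), matrix(rnorm(20), 2, 10))
  rownames(yv) <- NULL
  Fp <- tiny_F(fv)
  Yp <- tiny_Y(yv)
  st3 <- tiny_state(D = 3, N = 10, P = 4, K = 1)
  st3$Z[1, 1] <- 1; st3$V[1, 1] <- 1
  tr3 <- lcsens:::posterior_trace(list(st3), 0, cfg)
  tab3 <- lc_association_table(tr3, Yp, Fp)
  expect_equal(nrow(tab3), 1)
  expect_gt(tab3$rho, 0)
})

test_that("support F1 matches columns greedily and scores pooled overlap", {
  Zt <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(support_f1(Zt, Zt), 1)
  expect_equal(support_f1(Zt[, 2:1], Zt), 1)          # label permutation
  expect_equal(support_f1(matrix(0, 4, 2), Zt), 0)    # nothing recovered
  Ze <- cbind(c(1, 1, 1, 0), c(0, 0, 1, 1))           # one extra drug
  expect_equal(support_f1(Ze, Zt), 2 * 4 / (2 * 4 + 1))
})
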