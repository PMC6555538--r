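# Gibbs sampling for the sparse discriminative factor model. Every update is
# an exact draw from its full conditional; spike-and-slab indicators are
# flipped with the slab coefficient analytically integrated out, which is
# what makes the sampler mix without joint (Z, G) proposals.

# Single spike-and-slab site: posterior flip probability and slab conditional
# for a coefficient with unit-variance slab, observation precision `prec`,
# regressor sum of squares `ssx` and regressor-residual cross product `sxr`.
# log Bayes factor (slab vs spike) = -log(q)/2 + s^2/(2q), q = 1 + prec*ssx,
# s = prec*sxr; slab conditional is N(s/q, 1/q).
spike_slab_site <- function(prior_logodds, prec, ssx, sxr) {
  q <- 1 + prec * ssx
  s <- prec * sxr
  log_bf <- -0.5 * log(q) + 0.5 * s * s / q
  list(p1 = sigmoid(prior_logodds + log_bf),
       mean = s / q, sd = sqrt(1 / q), log_bf = log_bf)
}

# --- core updates on plain matrices -----------------------------------------

# Z/G: for each (d, k), flip Z[d,k] from its full conditional (slab
# integrated out, masked entries skipped, MRF neighbors added to the prior
# log-odds), then redraw G[d,k] from its conjugate Gaussian where active.
upd_loadings_core <- function(state, Y0, Mnum, nl, all_obs) {
  D <- nrow(state$Z); K <- state$K
  Z <- state$Z; G <- state$G; X <- state$X
  lam_y <- state$lam_y; v <- state$v
  R <- Y0 - G %*% X
  has_graph <- any(lengths(nl$nbr) > 0)
  for (k in seq_len(K)) {
    xk <- X[k, ]
    if (all_obs) {
      xsq <- rep(sum(xk * xk), D)
      cross <- as.vector(R %*% xk) + G[, k] * xsq
    } else {
      xsq <- as.vector(Mnum %*% (xk * xk))
      cross <- as.vector((R * Mnum) %*% xk) + G[, k] * xsq
    }
    base <- log(v[k]) - log1p(-v[k])
    site <- spike_slab_site(base, lam_y, xsq, cross)
    gold <- G[, k]
    u <- stats::runif(D)
    for (d in seq_len(D)) {
      p1 <- if (has_graph && length(nl$nbr[[d]]) > 0)
        sigmoid(base + sum(nl$wt[[d]] * Z[nl$nbr[[d]], k]) + site$log_bf[d])
      else site$p1[d]
      if (u[d] < p1) {
        Z[d, k] <- 1
        G[d, k] <- site$mean[d] + stats::rnorm(1) * site$sd[d]
      } else {
        Z[d, k] <- 0
        G[d, k] <- 0
      }
    }
    dg <- gold - G[, k]
    if (any(dg != 0)) R <- R + outer(dg, xk)
  }
  state$Z <- Z; state$G <- G
  state
}

# V/B: same scheme against the partial residual of X's rows, regressors are
# feature rows of F, prior log-odds from pi_p plus feature-MRF neighbors.
# Flips within a row change the residual seen by later features, so the scan
# is sequential; the cross product X_k . f_p - B_k (F F')_p is maintained
# incrementally through the feature gram matrix when it fits (P <= N),
# otherwise through a running length-N residual.
upd_regression_core <- function(state, Fv, Fss, nl, FFt = NULL) {
  K <- state$K; P <- nrow(Fv)
  V <- state$V; B <- state$B; X <- state$X
  lam_x <- state$lam_x
  lo_pi <- log(state$pi) - log1p(-state$pi)
  has_graph <- any(lengths(nl$nbr) > 0)
  use_gram <- !is.null(FFt)
  if (use_gram) {
    XFt <- X %*% t(Fv)              # K x P
  } else {
    tF <- t(Fv)
    Rx <- X - B %*% Fv
  }
  for (k in seq_len(K)) {
    lamk <- lam_x[k]
    if (use_gram) {
      cvec <- as.vector(B[k, ] %*% FFt)
    } else {
      r <- Rx[k, ]
    }
    u <- stats::runif(P)
    for (p in seq_len(P)) {
      cross <- if (use_gram)
        XFt[k, p] - cvec[p] + B[k, p] * Fss[p]
      else
        sum(r * tF[, p]) + B[k, p] * Fss[p]
      lo_prior <- if (has_graph && length(nl$nbr[[p]]) > 0)
        lo_pi[p] + sum(nl$wt[[p]] * V[k, nl$nbr[[p]]])
      else lo_pi[p]
      site <- spike_slab_site(lo_prior, lamk, Fss[p], cross)
      bold <- B[k, p]
      if (u[p] < site$p1) {
        V[k, p] <- 1
        bnew <- site$mean + stats::rnorm(1) * site$sd
      } else {
        V[k, p] <- 0
        bnew <- 0
      }
      if (bnew != bold) {
        if (use_gram) cvec <- cvec + (bnew - bold) * FFt[p, ]
        else r <- r + (bold - bnew) * tF[, p]
      }
      B[k, p] <- bnew
    }
  }
  state$V <- V; state$B <- B
  state
}

# X: exact multivariate Gaussian full conditional per cell-line column;
# precision diag(lam_x) + G' diag(lam_y * mask) G. With no missing entries
# the precision is shared by all columns, so one Cholesky serves all N.
upd_latent_core <- function(state, Y0, Mnum, Fv, all_obs) {
  K <- state$K; N <- ncol(Y0)
  G <- state$G; lam_y <- state$lam_y; lam_x <- state$lam_x
  BF <- state$B %*% Fv
  if (all_obs) {
    A <- diag(lam_x, nrow = K) + crossprod(G * sqrt(lam_y))
    C <- chol(A)
    rhs <- crossprod(G, lam_y * Y0) + lam_x * BF
    mu <- backsolve(C, forwardsolve(t(C), rhs))
    state$X <- mu + backsolve(C, matrix(stats::rnorm(K * N), K, N))
  } else {
    X <- state$X
    for (n in seq_len(N)) {
      m <- Mnum[, n]
      Gm <- G * sqrt(lam_y * m)
      A <- diag(lam_x, nrow = K) + crossprod(Gm)
      C <- chol(A)
      rhs <- crossprod(G, lam_y * m * Y0[, n]) + lam_x * BF[, n]
      mu <- backsolve(C, forwardsolve(t(C), rhs))
      X[, n] <- mu + backsolve(C, stats::rnorm(K))
    }
    state$X <- X
  }
  state
}

# v, pi: conjugate Beta draws from the column/feature inclusion counts. The
# MRF terms do not involve v or pi, so conjugacy is unaffected.
upd_sparsity_core <- function(state, alpha_over_K, beta_over_P) {
  D <- nrow(state$Z); K <- state$K; P <- ncol(state$V)
  m_k <- colSums(state$Z)
  state$v <- clamp01(stats::rbeta(K, alpha_over_K + m_k, 1 + D - m_k))
  s_p <- colSums(state$V)
  state$pi <- clamp01(stats::rbeta(P, beta_over_P + s_p, 1 + K - s_p))
  state
}

# Precisions and their shared rate hyperparameters: all conjugate Gamma under
# the shape/scale reading of the hierarchical prior (lam | b ~ Exp(rate b),
# b ~ Exp(1)).
upd_noise_core <- function(state, Y0, Mnum, Fv, n_d, all_obs) {
  D <- nrow(state$Z); K <- state$K; N <- ncol(Y0)
  res <- Y0 - state$G %*% state$X
  if (!all_obs) res <- res * Mnum
  rss_y <- rowSums(res^2)
  state$lam_y <- stats::rgamma(D, 1 + n_d / 2,
                               rate = state$b_y + rss_y / 2)
  state$b_y <- stats::rgamma(1, 1 + D, rate = 1 + sum(state$lam_y))
  rss_x <- rowSums((state$X - state$B %*% Fv)^2)
  state$lam_x <- stats::rgamma(K, 1 + N / 2,
                               rate = state$b_x + rss_x / 2)
  state$b_x <- stats::rgamma(1, 1 + K, rate = 1 + sum(state$lam_x))
  state
}

# One full sweep in the fixed scan order. `dat` carries precomputed
# quantities shared across sweeps.
gibbs_sweep <- function(state, dat) {
  state <- upd_latent_core(state, dat$Y0, dat$Mnum, dat$Fv, dat$all_obs)
  state <- upd_loadings_core(state, dat$Y0, dat$Mnum, dat$nlD, dat$all_obs)
  state <- upd_regression_core(state, dat$Fv, dat$Fss, dat$nlP, dat$FFt)
  state <- upd_sparsity_core(state, dat$alpha_over_K, dat$beta_over_P)
  state <- upd_noise_core(state, dat$Y0, dat$Mnum, dat$Fv, dat$n_d,
                          dat$all_obs)
  state
}

# Assemble the precomputed-data bundle used by gibbs_sweep.
make_sweep_data <- function(Yv, mask, Fv, hp, drug_graph = NULL,
                            feat_graph = NULL) {
  D <- nrow(Yv); N <- ncol(Yv); P <- nrow(Fv)
  Y0 <- Yv; Y0[!mask] <- 0
  Mnum <- matrix(as.numeric(mask), D, N)
  FFt <- if (P <= max(N, 512)) tcrossprod(Fv) else NULL
  list(Y0 = Y0, Mnum = Mnum, Fv = Fv, Fss = rowSums(Fv^2), FFt = FFt,
       n_d = rowSums(Mnum), all_obs = all(mask),
       nlD = neighbor_list(drug_graph, D),
       nlP = neighbor_list(feat_graph, P),
       alpha_over_K = hp$alpha / hp$k_max,
       beta_over_P = resolve_beta(hp, P) / P)
}

# --- user-facing single updates ---------------------------------------------

state_hp <- function(state) {
  hp <- attr(state, "hp")
  if (is.null(hp)) stop("state carries no hyperparameters (attr 'hp')")
  hp
}

#' Resample the drug loadings (Z, G) from their full conditional
#'
#' @param state a `latent_state` (carrying its hyperparameters).
#' @param Y a [sensitivity_matrix()].
#' @param drug_graph optional [relation_graph()] over drugs.
#' @return the updated state.
#' @export
update_loadings <- function(state, Y, drug_graph = NULL) {
  dat <- make_sweep_data(Y$values, Y$observed_mask,
                         matrix(0, 1, ncol(Y$values)), state_hp(state),
                         drug_graph = drug_graph)
  upd_loadings_core(state, dat$Y0, dat$Mnum, dat$nlD, dat$all_obs)
}

#' Resample the feature regression (V, B) from its full conditional
#'
#' @param state a `latent_state`.
#' @param F a [feature_matrix()].
#' @param feat_graph optional [relation_graph()] over features.
#' @return the updated state.
#' @export
update_regression <- function(state, F, feat_graph = NULL) {
  Fv <- F$values
  nl <- neighbor_list(feat_graph, nrow(Fv))
  upd_regression_core(state, Fv, rowSums(Fv^2), nl, tcrossprod(Fv))
}

#' Resample the latent characteristic values X from their full conditional
#'
#' @param state a `latent_state`.
#' @param Y a [sensitivity_matrix()].
#' @param F a [feature_matrix()].
#' @return the updated state.
#' @export
update_latent <- function(state, Y, F) {
  mask <- Y$observed_mask
  Y0 <- Y$values; Y0[!mask] <- 0
  upd_latent_core(state, Y0, matrix(as.numeric(mask), nrow(Y0), ncol(Y0)),
                  F$values, all(mask))
}

#' Resample the sparsity rates v and pi from their conjugate conditionals
#'
#' @param state a `latent_state`.
#' @return the updated state.
#' @export
update_sparsity <- function(state) {
  hp <- state_hp(state)
  P <- ncol(state$V)
  upd_sparsity_core(state, hp$alpha / hp$k_max, resolve_beta(hp, P) / P)
}

#' Resample noise precisions and their rate hyperparameters
#'
#' @param state a `latent_state`.
#' @param Y a [sensitivity_matrix()].
#' @param F a [feature_matrix()].
#' @return the updated state.
#' @export
update_noise <- function(state, Y, F) {
  mask <- Y$observed_mask
  Y0 <- Y$values; Y0[!mask] <- 0
  Mnum <- matrix(as.numeric(mask), nrow(Y0), ncol(Y0))
  upd_noise_core(state, Y0, Mnum, F$values, rowSums(Mnum), all(mask))
}

# --- driver -----------------------------------------------------------------

#' Fit the model by Gibbs sampling
#'
#' Standardizes the data (per-drug z-scoring of the sensitivity rows and of
#' the continuous feature rows; mutation rows left binary), initializes the
#' chain from the prior, and performs `cfg$n_iter` full Gibbs sweeps in the
#' fixed order latent values, drug loadings, feature regression, sparsity
#' rates, noise precisions. Every `cfg$thin`-th post-burn-in state is
#' recorded together with its log joint density. The returned trace carries
#' the training standardization statistics, which [predict_mean()] applies
#' to held-out data.
#'
#' @param Y a [sensitivity_matrix()].
#' @param F a [feature_matrix()]; cell lines are aligned to `Y` by label.
#' @param cfg a [gibbs_config()].
#' @param drug_graph,feat_graph optional [relation_graph()]s over the drugs
#'   and features (used only if the corresponding `use_*_mrf` flag in `cfg`
#'   is `TRUE`).
#' @param standardize if `FALSE`, fit the data as given (no z-scoring).
#' @param verbose if `TRUE`, report progress (sweep, active-LC count, log
#'   joint) roughly every 10% of iterations.
#'
#' @return a `posterior_trace`.
#' @export
run_gibbs <- function(Y, F, cfg = gibbs_config(), drug_graph = NULL,
                      feat_graph = NULL, standardize = TRUE,
                      verbose = FALSE) {
  stopifnot(inherits(Y, "sensitivity_matrix"), inherits(F, "feature_matrix"),
            inherits(cfg, "gibbs_config"))
  F <- align_cells(Y, F)
  D <- nrow(Y$values); N <- ncol(Y$values); P <- nrow(F$values)
  hp <- cfg$hp
  if (!cfg$use_drug_mrf) drug_graph <- NULL
  if (!cfg$use_feature_mrf) feat_graph <- NULL
  if (!is.null(drug_graph) && drug_graph$n_nodes != D)
    stop("drug_graph has ", drug_graph$n_nodes, " nodes; expected ", D)
  if (!is.null(feat_graph) && feat_graph$n_nodes != P)
    stop("feat_graph has ", feat_graph$n_nodes, " nodes; expected ", P)

  if (standardize) {
    y_stats <- row_standardize_stats(Y$values, Y$observed_mask)
    f_stats <- row_standardize_stats(F$values,
                                     skip = F$kind_of == "mutation")
  } else {
    y_stats <- list(center = rep(0, D), scale = rep(1, D))
    f_stats <- list(center = rep(0, P), scale = rep(1, P))
  }
  Yv <- apply_row_standardization(Y$values, y_stats)
  Fv <- apply_row_standardization(F$values, f_stats)

  dat <- make_sweep_data(Yv, Y$observed_mask, Fv, hp, drug_graph, feat_graph)
  Ystd <- Y; Ystd$values <- Yv
  Fstd <- F; Fstd$values <- Fv

  set.seed(cfg$seed)
  state <- init_state(D, N, P, hp, F_values = Fv, support = "empty")
  attr(state, "hp") <- hp

  states <- vector("list", 0)
  ljs <- numeric(0)
  report_at <- unique(pmax(1L, round(seq_len(10) / 10 * cfg$n_iter)))
  for (iter in seq_len(cfg$n_iter)) {
    state <- gibbs_sweep(state, dat)
    post <- iter - cfg$burn_in
    if (post >= 1 && post %% cfg$thin == 0) {
      states[[length(states) + 1L]] <- state
      ljs <- c(ljs, log_joint(state, Ystd, Fstd, drug_graph, feat_graph))
    }
    if (verbose && iter %in% report_at) {
      message(sprintf("sweep %d/%d: active LCs = %d", iter, cfg$n_iter,
                      active_lc_count(state$Z)))
    }
  }
  if (length(states) == 0) {
    states <- list(state)
    ljs <- log_joint(state, Ystd, Fstd, drug_graph, feat_graph)
  }
  counts <- vapply(states, function(s) active_lc_count(s$Z), numeric(1))
  if (max(counts) >= hp$k_max)
    warning("active LC count reached the truncation level k_max = ",
            hp$k_max, "; consider increasing k_max")
  posterior_trace(states, ljs, cfg,
                  drug_ids = Y$drug_ids, cell_ids = Y$cell_ids,
                  feature_ids = F$feature_ids,
                  standardization = list(y_center = y_stats$center,
                                         y_scale = y_stats$scale,
                                         f_center = f_stats$center,
                                         f_scale = f_stats$scale))
}
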