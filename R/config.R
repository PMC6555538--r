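#' Model hyperparameters
#'
#' @param alpha Indian-buffet-process concentration (> 0). Controls the prior
#'   expected number of latent characteristics (LCs) used per drug; the prior
#'   expected number of non-empty LCs approaches `alpha * sum(1/d)` for `d`
#'   in `1:D` as the truncation grows.
#' @param beta feature-sparsity concentration (> 0). Each feature's inclusion
#'   rate is `pi_p ~ Beta(beta/P, 1)`, so `beta` is roughly the prior
#'   expected number of features used per LC summed over features. `NULL`
#'   (default) resolves to `0.01 * P` at fit time so the prior expected
#'   number of active features per LC stays small regardless of `P`.
#' @param k_max truncation level of the finite IBP approximation (>= 1).
#'   Empty columns cost almost nothing and can be re-born, so `k_max` only
#'   needs headroom above the number of LCs supported by the data; the fit
#'   warns if the active count reaches `k_max`.
#' @param mrf_weight default edge weight used when building relation graphs.
#'
#' @return an object of class `lc_hyperparams`.
#' @export
hyperparams <- function(alpha = 2, beta = NULL, k_max = 50, mrf_weight = 1) {
  stopifnot(alpha > 0, k_max >= 1, mrf_weight > 0)
  if (!is.null(beta)) stopifnot(beta > 0)
  structure(list(alpha = alpha, beta = beta, k_max = as.integer(k_max),
                 mrf_weight = mrf_weight),
            class = "lc_hyperparams")
}

# Resolve the data-dependent default for beta.
resolve_beta <- function(hp, P) if (is.null(hp$beta)) 0.01 * P else hp$beta

#' Gibbs sampler configuration
#'
#' @param n_iter total number of full Gibbs sweeps (default 10000).
#' @param burn_in sweeps discarded before recording (default 5000);
#'   must be `< n_iter`.
#' @param thin record every `thin`-th post-burn-in sweep (default 10).
#' @param seed integer RNG seed; identical seeds and inputs give bit-identical
#'   traces.
#' @param hp model hyperparameters, see [hyperparams()].
#' @param use_drug_mrf,use_feature_mrf logical; whether a supplied relation
#'   graph is actually used in the prior (`TRUE` by default).
#'
#' @return an object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 10000, burn_in = 5000, thin = 10, seed = 1,
                         hp = hyperparams(), use_drug_mrf = TRUE,
                         use_feature_mrf = TRUE) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1,
            inherits(hp, "lc_hyperparams"))
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), hp = hp,
                 use_drug_mrf = isTRUE(use_drug_mrf),
                 use_feature_mrf = isTRUE(use_feature_mrf)),
            class = "gibbs_config")
}

#' Simulation configuration for the generative model
#'
#' Defaults describe the reference synthetic study: 20 drugs, 300 cell lines
#' and 40 genomic features generated by 3 true latent characteristics at high
#' signal-to-noise (noise precisions 25, i.e. noise s.d. 0.2 against unit
#' slab scale).
#'
#' @param D,N,P,K_true numbers of drugs, cell lines, features and true LCs;
#'   `K_true <= min(D, P)` is required.
#' @param drugs_per_lc,features_per_lc support sizes drawn without
#'   replacement for each true LC (fixed-size mode, the default).
#' @param z_density,v_density if non-`NULL`, switch to Bernoulli support
#'   mode: each `Z`/`V` entry is included independently with this
#'   probability instead of using fixed support sizes.
#' @param noise_prec_y,noise_prec_x noise precisions on the sensitivity
#'   matrix and on the latent characteristics.
#' @param frac_binary_features fraction of feature rows thresholded to 0/1 to
#'   mimic mutation indicators.
#' @param binary_threshold_q quantile at which binary features are
#'   thresholded (default 0.9: mutations are rare, ~10% of cell lines).
#' @param seed integer RNG seed.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(D = 20, N = 300, P = 40, K_true = 3,
                       drugs_per_lc = 5, features_per_lc = 5,
                       z_density = NULL, v_density = NULL,
                       noise_prec_y = 25, noise_prec_x = 25,
                       frac_binary_features = 0.25,
                       binary_threshold_q = 0.9, seed = 1) {
  D <- as.integer(D); N <- as.integer(N); P <- as.integer(P)
  K_true <- as.integer(K_true)
  stopifnot(D >= 1, N >= 1, P >= 1, K_true >= 1, K_true <= min(D, P),
            noise_prec_y > 0, noise_prec_x > 0,
            frac_binary_features >= 0, frac_binary_features <= 1,
            binary_threshold_q > 0, binary_threshold_q < 1)
  if (is.null(z_density)) {
    drugs_per_lc <- as.integer(drugs_per_lc)
    stopifnot(drugs_per_lc >= 1, drugs_per_lc <= D)
  } else stopifnot(z_density > 0, z_density <= 1)
  if (is.null(v_density)) {
    features_per_lc <- as.integer(features_per_lc)
    stopifnot(features_per_lc >= 1, features_per_lc <= P)
  } else stopifnot(v_density > 0, v_density <= 1)
  structure(list(D = D, N = N, P = P, K_true = K_true,
                 drugs_per_lc = drugs_per_lc,
                 features_per_lc = features_per_lc,
                 z_density = z_density, v_density = v_density,
                 noise_prec_y = noise_prec_y, noise_prec_x = noise_prec_x,
                 frac_binary_features = frac_binary_features,
                 binary_threshold_q = binary_threshold_q,
                 seed = as.integer(seed)),
            class = "sim_config")
}
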