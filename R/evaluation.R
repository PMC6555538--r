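#' Proportion of held-out variance explained
#'
#' `1 - SS_res / SS_tot`, pooled over all observed held-out entries, with
#' the per-drug training means as the null prediction in `SS_tot`. Can be
#' negative when predictions are worse than the training-mean baseline.
#'
#' @param y_obs `D x M` matrix of held-out observations (`NA` = missing).
#' @param y_pred `D x M` matrix of predictions.
#' @param train_row_means length-`D` per-drug means computed on training
#'   data only.
#' @param mask optional logical `D x M` observation mask; defaults to
#'   `!is.na(y_obs)`.
#'
#' @return pooled PVE (a real number, at most 1).
#' @export
pve <- function(y_obs, y_pred, train_row_means, mask = NULL) {
  y_obs <- as.matrix(y_obs); y_pred <- as.matrix(y_pred)
  stopifnot(all(dim(y_obs) == dim(y_pred)),
            length(train_row_means) == nrow(y_obs))
  if (is.null(mask)) mask <- !is.na(y_obs)
  if (sum(mask) < 2) stop("need at least 2 observed held-out entries")
  res <- (y_obs - y_pred)[mask]
  null_res <- (y_obs - train_row_means)[mask]   # column-recycled row means
  ss_tot <- sum(null_res^2)
  if (ss_tot == 0) stop("held-out observations equal the training means everywhere (SS_tot = 0)")
  1 - sum(res^2) / ss_tot
}

#' Concordance index
#'
#' Probability that a randomly chosen pair of cell lines with distinct
#' observed sensitivities is ranked in the same order by the predictions.
#' Prediction ties score 1/2; pairs with tied observations are excluded.
#'
#' @param y_obs,y_pred numeric vectors of equal length (>= 2).
#' @return c-index in `[0, 1]`.
#' @export
concordance_index <- function(y_obs, y_pred) {
  keep <- !is.na(y_obs) & !is.na(y_pred)
  y_obs <- y_obs[keep]; y_pred <- y_pred[keep]
  M <- length(y_obs)
  if (M < 2) stop("need at least 2 paired observations")
  score <- 0; npair <- 0
  for (i in seq_len(M - 1)) {
    for (j in seq((i + 1), M)) {
      if (y_obs[i] == y_obs[j]) next
      npair <- npair + 1
      dp <- (y_pred[i] - y_pred[j]) * (y_obs[i] - y_obs[j])
      score <- score + if (dp > 0) 1 else if (dp == 0) 0.5 else 0
    }
  }
  if (npair == 0) stop("all observations tied; c-index undefined")
  score / npair
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using average ranks for ties; the two-sided p-value uses
#' the t approximation `t = rho * sqrt((M - 2) / (1 - rho^2))` on `M - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `M >= 3`.
#' @return list with `rho` and `p` (clamped into `(0, 1]`).
#' @export
spearman_rho_p <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance; Spearman correlation undefined")
  rho <- stats::cor(rx, ry)
  M <- length(x)
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((M - 2) / (1 - rho^2))
    p <- max(2 * stats::pt(-abs(tstat), df = M - 2), .Machine$double.xmin)
  }
  list(rho = rho, p = min(p, 1))
}

#' Cell-line-holdout cross-validation
#'
#' Partitions the cell lines into `n_folds` disjoint folds by seeded
#' shuffle (fold sizes differ by at most one), refits the model on each
#' training set (standardization statistics computed on training columns
#' only) and evaluates predictions on the held-out columns.
#'
#' @param Y a [sensitivity_matrix()].
#' @param F a [feature_matrix()].
#' @param cfg a [gibbs_config()]; fold `f` uses a seed derived from
#'   `cfg$seed` and `f`, and `cfg$seed` fixes the fold assignment.
#' @param n_folds number of folds (default 10).
#' @param drug_graph,feat_graph optional [relation_graph()]s passed to the
#'   fit.
#' @param verbose passed through to [run_gibbs()].
#'
#' @return list of per-fold results, each with `fold_id`,
#'   `held_out_cell_ids`, `pve`, `mean_cindex` and `per_drug_cindex`
#'   (NA for drugs without a scoreable held-out pair).
#' @export
cross_validate <- function(Y, F, cfg = gibbs_config(), n_folds = 10,
                           drug_graph = NULL, feat_graph = NULL,
                           verbose = FALSE) {
  F <- align_cells(Y, F)
  N <- ncol(Y$values)
  n_folds <- as.integer(n_folds)
  stopifnot(N >= n_folds, n_folds >= 2)
  set.seed(derive_seed(cfg$seed, 0L))
  perm <- sample.int(N)
  fold_of <- integer(N)
  fold_of[perm] <- rep(seq_len(n_folds), length.out = N)  # sizes differ <= 1
  results <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    Ytr <- subset_cells(Y, train_idx)
    Ftr <- subset_cells(F, train_idx)
    Yte <- Y$values[, test_idx, drop = FALSE]
    mask_te <- Y$observed_mask[, test_idx, drop = FALSE]
    Fte <- subset_cells(F, test_idx)
    cfg_f <- cfg
    cfg_f$seed <- derive_seed(cfg$seed, f)
    trace <- run_gibbs(Ytr, Ftr, cfg_f, drug_graph = drug_graph,
                       feat_graph = feat_graph, verbose = verbose)
    pred <- predict_mean(trace, Fte)
    tr_means <- vapply(seq_len(nrow(Yv <- Ytr$values)), function(d)
      mean(Yv[d, Ytr$observed_mask[d, ]]), numeric(1))
    fold_pve <- pve(Yte, pred, tr_means, mask = mask_te)
    per_drug <- rep(NA_real_, nrow(Yte))
    for (d in seq_len(nrow(Yte))) {
      obs <- Yte[d, mask_te[d, ]]
      prd <- pred[d, mask_te[d, ]]
      if (length(obs) >= 2 && length(unique(obs)) >= 2)
        per_drug[d] <- concordance_index(obs, prd)
    }
    results[[f]] <- list(fold_id = f,
                         held_out_cell_ids = Y$cell_ids[test_idx],
                         pve = fold_pve,
                         mean_cindex = mean(per_drug, na.rm = TRUE),
                         per_drug_cindex = stats::setNames(per_drug,
                                                           Y$drug_ids))
  }
  results
}

#' Per-LC drug-feature association table
#'
#' Summarizes a trace by its maximum-log-joint state (LC labels are not
#' aligned across sweeps, so averaging is not meaningful for interpretation)
#' and, for every active LC, every drug loading on it and every feature it
#' uses, reports the Spearman correlation between that drug's observed
#' sensitivities and the feature values across cell lines.
#'
#' @param trace a `posterior_trace`.
#' @param Y a [sensitivity_matrix()] (original scale).
#' @param F a [feature_matrix()].
#' @param bh_adjust if `TRUE`, add a Benjamini-Hochberg adjusted p column.
#'
#' @return data frame with columns `lc_id`, `drug_id`, `feature_id`, `rho`,
#'   `p` (and `p_adj` when requested).
#' @export
lc_association_table <- function(trace, Y, F, bh_adjust = FALSE) {
  F <- align_cells(Y, F)
  best <- trace_best_state(trace)
  rows <- list()
  for (k in seq_len(best$K)) {
    drugs <- which(best$Z[, k] == 1)
    feats <- which(best$V[k, ] == 1)
    if (length(drugs) == 0 || length(feats) == 0) next
    for (d in drugs) {
      obs <- Y$observed_mask[d, ]
      for (p in feats) {
        sp <- tryCatch(spearman_rho_p(Y$values[d, obs], F$values[p, obs]),
                       error = function(e) NULL)
        if (is.null(sp)) next
        rows[[length(rows) + 1L]] <-
          data.frame(lc_id = k, drug_id = Y$drug_ids[d],
                     feature_id = F$feature_ids[p],
                     rho = sp$rho, p = sp$p)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lc_id = integer(), drug_id = character(),
               feature_id = character(), rho = numeric(), p = numeric())
  if (bh_adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Support-recovery F1 after greedy LC matching
#'
#' Matches estimated LC columns to true columns greedily by pairwise F1
#' (without replacement), then pools true/false positives over all matched
#' and unmatched columns into a single F1 score for the binary support.
#'
#' @param Z_est,Z_true binary matrices with the same number of rows;
#'   empty estimated columns are ignored.
#' @return pooled F1 in `[0, 1]`.
#' @export
support_f1 <- function(Z_est, Z_true) {
  Z_est <- as.matrix(Z_est); Z_true <- as.matrix(Z_true)
  stopifnot(nrow(Z_est) == nrow(Z_true))
  Z_est <- Z_est[, colSums(Z_est != 0) > 0, drop = FALSE]
  ke <- ncol(Z_est); kt <- ncol(Z_true)
  pair_f1 <- matrix(0, ke, kt)
  if (ke > 0) {
    for (i in seq_len(ke)) for (j in seq_len(kt)) {
      tp <- sum(Z_est[, i] == 1 & Z_true[, j] == 1)
      pair_f1[i, j] <- 2 * tp / (sum(Z_est[, i]) + sum(Z_true[, j]))
    }
  }
  tp <- 0; fp <- 0; fn <- 0
  used_e <- rep(FALSE, ke); used_t <- rep(FALSE, kt)
  while (any(!used_e) && any(!used_t)) {
    m <- pair_f1
    m[used_e, ] <- -1; m[, used_t] <- -1
    idx <- arrayInd(which.max(m), dim(m))
    i <- idx[1]; j <- idx[2]
    used_e[i] <- TRUE; used_t[j] <- TRUE
    tp <- tp + sum(Z_est[, i] == 1 & Z_true[, j] == 1)
    fp <- fp + sum(Z_est[, i] == 1 & Z_true[, j] == 0)
    fn <- fn + sum(Z_est[, i] == 0 & Z_true[, j] == 1)
  }
  if (any(!used_e)) fp <- fp + sum(Z_est[, !used_e])
  if (any(!used_t)) fn <- fn + sum(Z_true[, !used_t])
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}
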