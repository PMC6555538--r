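#' Simulate a dataset from the generative model
#'
#' Runs the model forward: features are drawn i.i.d. standard normal (a
#' configurable fraction of rows is thresholded at a high quantile to 0/1 to
#' mimic rare mutation indicators), each true latent characteristic selects
#' a fixed-size support of drugs and features without replacement (or
#' Bernoulli supports when densities are given), slab coefficients are
#' standard normal, `X = B F + noise` and `Y = G X + noise` with the
#' configured precisions. Features are grouped into synthetic genes of size
#' 1-3; the returned relation graphs connect drugs sharing a true LC and
#' features belonging to the same gene.
#'
#' @param sc a [sim_config()].
#'
#' @return list with `Y` ([sensitivity_matrix()]), `F`
#'   ([feature_matrix()]), `truth` (a `latent_state` holding the generating
#'   configuration), `drug_graph`, `feat_graph`, and `config` (the echo of
#'   `sc`).
#' @export
simulate_lc_data <- function(sc = sim_config()) {
  stopifnot(inherits(sc, "sim_config"))
  set.seed(sc$seed)
  D <- sc$D; N <- sc$N; P <- sc$P; K <- sc$K_true

  # genomic features: continuous standard-normal rows; the last
  # frac_binary rows thresholded to rare 0/1 mutation indicators
  Fv <- matrix(stats::rnorm(P * N), P, N)
  n_bin <- round(sc$frac_binary_features * P)
  kind <- rep("expression", P)
  if (n_bin > 0) {
    bin_rows <- seq(P - n_bin + 1, P)
    thr <- stats::qnorm(sc$binary_threshold_q)
    Fv[bin_rows, ] <- (Fv[bin_rows, , drop = FALSE] > thr) * 1
    kind[bin_rows] <- "mutation"
  }
  # synthetic genes of size 1-3
  gene <- character(P)
  p <- 1; g <- 0
  while (p <= P) {
    g <- g + 1
    size <- sample(1:3, 1)
    idx <- p:min(p + size - 1, P)
    gene[idx] <- paste0("gene", g)
    p <- p + length(idx)
  }
  feature_ids <- paste0("feat", seq_len(P), "_",
                        c(expression = "e", cnv = "n", mutation = "m")[kind])

  # supports
  Z <- matrix(0, D, K); V <- matrix(0, K, P)
  for (k in seq_len(K)) {
    drugs <- if (is.null(sc$z_density))
      sample.int(D, sc$drugs_per_lc) else which(stats::runif(D) < sc$z_density)
    feats <- if (is.null(sc$v_density))
      sample.int(P, sc$features_per_lc) else which(stats::runif(P) < sc$v_density)
    Z[drugs, k] <- 1
    V[k, feats] <- 1
  }
  G <- Z * matrix(stats::rnorm(D * K), D, K)
  B <- V * matrix(stats::rnorm(K * P), K, P)
  X <- B %*% Fv + matrix(stats::rnorm(K * N), K, N) / sqrt(sc$noise_prec_x)
  Yv <- G %*% X + matrix(stats::rnorm(D * N), D, N) / sqrt(sc$noise_prec_y)

  drug_ids <- paste0("drug", seq_len(D))
  cell_ids <- paste0("cell", seq_len(N))
  Y <- sensitivity_matrix(Yv, drug_ids = drug_ids, cell_ids = cell_ids)
  F <- feature_matrix(Fv, feature_ids = feature_ids, gene_of = gene,
                      kind_of = kind, cell_ids = cell_ids)

  truth <- list(Z = Z, G = G, v = clamp01(colMeans(Z)), X = X, V = V, B = B,
                pi = clamp01(colMeans(V)),
                lam_y = rep(sc$noise_prec_y, D), b_y = 1,
                lam_x = rep(sc$noise_prec_x, K), b_x = 1, K = K)
  class(truth) <- "latent_state"

  # drugs sharing >= 1 true LC are linked
  share <- (Z %*% t(Z)) > 0
  ii <- integer(); jj <- integer()
  if (D >= 2) {
    for (a in seq_len(D - 1)) for (b in seq((a + 1), D))
      if (share[a, b]) { ii <- c(ii, a); jj <- c(jj, b) }
  }
  drug_graph <- relation_graph(D, data.frame(i = ii, j = jj,
                                             weight = rep(1, length(ii))),
                               node_ids = drug_ids)
  feat_graph <- build_gene_graph(stats::setNames(gene, feature_ids))

  list(Y = Y, F = F, truth = truth, drug_graph = drug_graph,
       feat_graph = feat_graph, config = sc)
}
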