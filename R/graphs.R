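#' Weighted undirected relation graph
#'
#' Sparse undirected graph over drugs (sharing inhibition targets) or over
#' genomic features (belonging to the same gene), used by the Markov random
#' field priors to couple sparsity patterns. Edges are stored once with
#' `i < j`; weights must be non-negative.
#'
#' @param n_nodes number of nodes (drugs or features).
#' @param edges data frame with integer columns `i`, `j` and numeric
#'   `weight`; pairs are normalized to `i < j`.
#' @param node_ids optional character labels for the nodes.
#'
#' @return an object of class `relation_graph`.
#' @export
relation_graph <- function(n_nodes,
                           edges = data.frame(i = integer(), j = integer(),
                                              weight = numeric()),
                           node_ids = NULL) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 0)
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    i <- as.integer(edges$i); j <- as.integer(edges$j)
    w <- as.numeric(edges$weight)
    if (any(i == j)) stop("self-loops are not allowed")
    if (any(i < 1L | j < 1L | i > n_nodes | j > n_nodes))
      stop("edge endpoints outside 1..n_nodes")
    if (any(w < 0)) stop("edge weights must be >= 0")
    lo <- pmin(i, j); hi <- pmax(i, j)
    if (anyDuplicated(cbind(lo, hi))) stop("duplicate edges")
    edges <- data.frame(i = lo, j = hi, weight = w)
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(i = integer(), j = integer(), weight = numeric())
  }
  if (!is.null(node_ids)) {
    node_ids <- as.character(node_ids)
    if (length(node_ids) != n_nodes) stop("node_ids length != n_nodes")
  }
  structure(list(n_nodes = n_nodes, edges = edges, node_ids = node_ids),
            class = "relation_graph")
}

#' @export
print.relation_graph <- function(x, ...) {
  cat(sprintf("relation_graph: %d nodes, %d edges\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

# Adjacency as parallel lists: nbr[[d]] = neighbor indices, wt[[d]] = weights.
# Used in the Gibbs inner loops; an absent/empty graph gives empty neighbor
# sets so the MRF term vanishes identically.
neighbor_list <- function(graph, n_nodes) {
  nbr <- rep(list(integer()), n_nodes)
  wt <- rep(list(numeric()), n_nodes)
  if (is.null(graph) || nrow(graph$edges) == 0)
    return(list(nbr = nbr, wt = wt))
  if (graph$n_nodes != n_nodes)
    stop("graph has ", graph$n_nodes, " nodes; expected ", n_nodes)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    i <- e$i[r]; j <- e$j[r]; w <- e$weight[r]
    nbr[[i]] <- c(nbr[[i]], j); wt[[i]] <- c(wt[[i]], w)
    nbr[[j]] <- c(nbr[[j]], i); wt[[j]] <- c(wt[[j]], w)
  }
  list(nbr = nbr, wt = wt)
}

#' Build a drug relation graph from target annotations
#'
#' Connects every unordered pair of drugs that share at least one inhibition
#' target, each edge receiving the same weight. This encodes "soft" prior
#' knowledge: linked drugs are encouraged, not forced, to load on the same
#' latent characteristics.
#'
#' @param drug_targets named list; each element is a character vector of
#'   target labels for one drug. Names are the drug ids (graph node order).
#' @param weight edge weight (>= 0) applied to every edge.
#'
#' @return a [relation_graph()] over the drugs.
#' @export
build_target_graph <- function(drug_targets, weight = 1) {
  stopifnot(is.list(drug_targets), weight >= 0)
  ids <- names(drug_targets)
  if (is.null(ids) || anyDuplicated(ids)) stop("drug_targets must have unique names")
  n <- length(drug_targets)
  ii <- integer(); jj <- integer()
  if (n >= 2) {
    for (a in seq_len(n - 1)) {
      for (b in seq((a + 1), n)) {
        if (length(intersect(drug_targets[[a]], drug_targets[[b]])) > 0) {
          ii <- c(ii, a); jj <- c(jj, b)
        }
      }
    }
  }
  relation_graph(n, data.frame(i = ii, j = jj,
                               weight = rep(weight, length(ii))),
                 node_ids = ids)
}

#' Build a feature relation graph from gene annotations
#'
#' Connects every pair of genomic features mapped to the same gene (for
#' example the expression, copy-number and mutation features of one gene),
#' each edge receiving the same weight.
#'
#' @param feature_genes named character vector mapping feature id -> gene.
#' @param weight edge weight (>= 0) applied to every edge.
#'
#' @return a [relation_graph()] over the features.
#' @export
build_gene_graph <- function(feature_genes, weight = 1) {
  stopifnot(weight >= 0)
  ids <- names(feature_genes)
  if (is.null(ids) || anyDuplicated(ids))
    stop("feature_genes must have unique names")
  n <- length(feature_genes)
  groups <- split(seq_len(n), as.character(feature_genes))
  ii <- integer(); jj <- integer()
  for (g in groups) {
    if (length(g) >= 2) {
      cmb <- utils::combn(sort(g), 2)
      ii <- c(ii, cmb[1, ]); jj <- c(jj, cmb[2, ])
    }
  }
  relation_graph(n, data.frame(i = ii, j = jj,
                               weight = rep(weight, length(ii))),
                 node_ids = ids)
}
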