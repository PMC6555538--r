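#' Read / write labeled matrices
#'
#' Matrices are stored as delimited text with the first row holding column
#' (cell line) labels and the first column holding row labels; empty cells
#' are missing values. The delimiter is inferred from the extension
#' (`.csv` = comma, anything else = tab). Writing then reading reproduces
#' labels, values and missingness exactly.
#'
#' @param path file path.
#' @return `read_matrix`: a numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("matrix file needs a label column and >= 1 data column: ", path)
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels))
    stop("duplicate row labels in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  if (anyDuplicated(colnames(m)))
    stop("duplicate column labels in ", path)
  m
}

#' @rdname read_matrix
#' @param m numeric matrix with row and column names.
#' @return `write_matrix`: `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("col", seq_len(ncol(m)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Active area of a dose-response curve
#'
#' Integrated area above the viability curve: the trapezoidal integral of
#' `max(0, 1 - viability)` over `log10(dose)`. Units are inhibition x dose
#' decades; a fully inactive drug scores 0 and full inhibition over a
#' `d`-decade dose range scores `d`. Unlike IC50 this summary is defined
#' even when 50% inhibition is never reached, and it reflects efficacy
#' across the whole tested range.
#'
#' @param doses strictly increasing positive concentrations (length >= 2).
#' @param viability fractions of control viability at each dose (values
#'   above 1 are treated as no inhibition).
#'
#' @return non-negative active area.
#' @export
active_area <- function(doses, viability) {
  stopifnot(length(doses) == length(viability), length(doses) >= 2)
  if (any(doses <= 0)) stop("doses must be positive")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  x <- log10(doses)
  y <- pmax(0, 1 - viability)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# --- trace serialization ----------------------------------------------------

#' Serialize / load a posterior trace
#'
#' A trace is written as a directory of per-snapshot flat TSV files (one per
#' matrix: Z, G, X, V, B) plus a JSON manifest holding dimensions, labels,
#' the scalar state components per snapshot, log-joint values, the
#' standardization statistics and the configuration echo.
#'
#' @param trace a `posterior_trace`.
#' @param dir directory to create/populate.
#' @return `write_trace`: `dir` invisibly; `read_trace`: a
#'   `posterior_trace`.
#' @export
write_trace <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  S <- length(trace$states)
  scalars <- lapply(trace$states, function(s)
    list(v = s$v, pi = s$pi, lam_y = s$lam_y, b_y = s$b_y,
         lam_x = s$lam_x, b_x = s$b_x))
  s1 <- trace$states[[1]]
  cfg <- trace$config_echo
  manifest <- list(n_states = S,
                   dims = list(D = nrow(s1$Z), K = s1$K,
                               N = ncol(s1$X), P = ncol(s1$B)),
                   drug_ids = trace$drug_ids, cell_ids = trace$cell_ids,
                   feature_ids = trace$feature_ids,
                   log_joint = trace$log_joint,
                   standardization = trace$standardization,
                   scalars = scalars,
                   config = list(n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                                 thin = cfg$thin, seed = cfg$seed,
                                 use_drug_mrf = cfg$use_drug_mrf,
                                 use_feature_mrf = cfg$use_feature_mrf,
                                 alpha = cfg$hp$alpha, beta = cfg$hp$beta,
                                 k_max = cfg$hp$k_max,
                                 mrf_weight = cfg$hp$mrf_weight))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (s in seq_len(S)) {
    st <- trace$states[[s]]
    for (nm in c("Z", "G", "X", "V", "B")) {
      utils::write.table(st[[nm]],
                         file.path(dir, sprintf("state%04d_%s.tsv", s, nm)),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_trace
#' @export
read_trace <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  S <- mf$n_states
  dims <- mf$dims
  cfg <- gibbs_config(n_iter = mf$config$n_iter, burn_in = mf$config$burn_in,
                      thin = mf$config$thin, seed = mf$config$seed,
                      hp = hyperparams(alpha = mf$config$alpha,
                                       beta = mf$config$beta,
                                       k_max = mf$config$k_max,
                                       mrf_weight = mf$config$mrf_weight),
                      use_drug_mrf = mf$config$use_drug_mrf,
                      use_feature_mrf = mf$config$use_feature_mrf)
  read_m <- function(path) as.matrix(utils::read.table(path, sep = "\t",
                                                       header = FALSE))
  states <- vector("list", S)
  sc_list <- mf$scalars
  for (s in seq_len(S)) {
    st <- list()
    for (nm in c("Z", "G", "X", "V", "B")) {
      m <- read_m(file.path(dir, sprintf("state%04d_%s.tsv", s, nm)))
      dimnames(m) <- NULL
      st[[nm]] <- m
    }
    sc <- if (is.data.frame(sc_list)) lapply(sc_list, `[[`, s) else sc_list[[s]]
    st$v <- as.numeric(unlist(sc$v)); st$pi <- as.numeric(unlist(sc$pi))
    st$lam_y <- as.numeric(unlist(sc$lam_y)); st$b_y <- as.numeric(sc$b_y[[1]])
    st$lam_x <- as.numeric(unlist(sc$lam_x)); st$b_x <- as.numeric(sc$b_x[[1]])
    st$K <- dims$K
    class(st) <- "latent_state"
    attr(st, "hp") <- cfg$hp
    states[[s]] <- st
  }
  std <- mf$standardization
  if (!is.null(std)) std <- lapply(std, as.numeric)
  posterior_trace(states, as.numeric(mf$log_joint), cfg,
                  drug_ids = mf$drug_ids, cell_ids = mf$cell_ids,
                  feature_ids = mf$feature_ids, standardization = std)
}

# --- annotation files -------------------------------------------------------

# Two-column TSV drug<TAB>target (one row per pair) -> named list of targets.
read_drug_targets <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("drug-target file needs two columns: ", path)
  split(as.character(df[[2]]), factor(as.character(df[[1]]),
                                      levels = unique(as.character(df[[1]]))))
}

# Two-column TSV feature<TAB>gene -> named character vector.
read_feature_genes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("feature-gene file needs two columns: ", path)
  if (anyDuplicated(df[[1]])) stop("duplicate feature ids in ", path)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

# Write a simulated bundle (Y, F, annotations, truth, graphs, config echo).
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sim$Y$values, file.path(dir, "Y.tsv"))
  write_matrix(sim$F$values, file.path(dir, "F.tsv"))
  utils::write.table(data.frame(feature = sim$F$feature_ids,
                                gene = sim$F$gene_of,
                                kind = sim$F$kind_of),
                     file.path(dir, "feature_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in c("Z", "G", "V", "B", "X"))
    utils::write.table(sim$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  for (gnm in c("drug_graph", "feat_graph"))
    utils::write.table(sim[[gnm]]$edges, file.path(dir, paste0(gnm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
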