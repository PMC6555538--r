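#' Drug-by-cell-line sensitivity matrix
#'
#' Container for continuous drug sensitivity scores (typically active-area
#' summaries of dose-response curves) for `D` drugs measured across `N` cell
#' lines. Missing measurements are encoded as `NA` and tracked in
#' `observed_mask`; they are excluded from all likelihood computations, which
#' is valid because the model's noise is diagonal per drug and so the
#' likelihood factorizes over entries.
#'
#' @param values numeric `D x N` matrix; `NA` marks unmeasured drug/cell
#'   pairs.
#' @param drug_ids character vector of `D` unique drug labels; defaults to
#'   the rownames of `values`.
#' @param cell_ids character vector of `N` unique cell-line labels; defaults
#'   to the colnames of `values`.
#'
#' @return an object of class `sensitivity_matrix` with fields `values`,
#'   `drug_ids`, `cell_ids` and logical `observed_mask`.
#' @export
sensitivity_matrix <- function(values, drug_ids = rownames(values),
                               cell_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  D <- nrow(values); N <- ncol(values)
  if (is.null(drug_ids)) drug_ids <- paste0("drug", seq_len(D))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(N))
  drug_ids <- as.character(drug_ids); cell_ids <- as.character(cell_ids)
  if (length(drug_ids) != D)
    stop("drug_ids length (", length(drug_ids), ") != number of rows (", D, ")")
  if (length(cell_ids) != N)
    stop("cell_ids length (", length(cell_ids), ") != number of columns (", N, ")")
  if (anyDuplicated(drug_ids)) stop("duplicate drug_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (any(!is.na(values) & !is.finite(values)))
    stop("non-finite (Inf/NaN) sensitivity values; use NA for missing entries")
  mask <- !is.na(values)
  if (any(rowSums(mask) == 0))
    stop("drug(s) with no observed entries: ",
         paste(drug_ids[rowSums(mask) == 0], collapse = ", "))
  if (any(colSums(mask) == 0))
    stop("cell line(s) with no observed entries: ",
         paste(cell_ids[colSums(mask) == 0], collapse = ", "))
  dimnames(values) <- list(drug_ids, cell_ids)
  structure(list(values = values, drug_ids = drug_ids, cell_ids = cell_ids,
                 observed_mask = mask),
            class = "sensitivity_matrix")
}

#' Genomic-feature-by-cell-line matrix
#'
#' Container for `P` genomic features (gene expression, copy-number variation
#' and binary mutation indicators) across `N` cell lines. Each feature is
#' annotated with the gene it belongs to and its kind; features of kind
#' `"mutation"` must be 0/1 and are never standardized, while continuous
#' features are z-scored per row at fit time.
#'
#' @param values numeric `P x N` matrix with no missing entries.
#' @param feature_ids character vector of `P` unique feature labels.
#' @param gene_of character vector of `P` gene labels (several features may
#'   map to the same gene); defaults to `feature_ids`.
#' @param kind_of character vector of `P` values in
#'   `c("expression", "cnv", "mutation")`; defaults to `"expression"`.
#' @param cell_ids character vector of `N` unique cell-line labels.
#'
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_ids = rownames(values),
                           gene_of = NULL, kind_of = NULL,
                           cell_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  P <- nrow(values); N <- ncol(values)
  if (is.null(feature_ids)) feature_ids <- paste0("feat", seq_len(P))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(N))
  feature_ids <- as.character(feature_ids); cell_ids <- as.character(cell_ids)
  if (is.null(gene_of)) gene_of <- feature_ids
  if (is.null(kind_of)) kind_of <- rep("expression", P)
  gene_of <- as.character(gene_of); kind_of <- as.character(kind_of)
  if (length(feature_ids) != P) stop("feature_ids length != number of rows")
  if (length(cell_ids) != N) stop("cell_ids length != number of columns")
  if (length(gene_of) != P) stop("gene_of length != number of features")
  if (length(kind_of) != P) stop("kind_of length != number of features")
  if (anyDuplicated(feature_ids)) stop("duplicate feature_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (!all(kind_of %in% c("expression", "cnv", "mutation")))
    stop("kind_of values must be 'expression', 'cnv' or 'mutation'")
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature matrix must be complete and finite")
  mut <- kind_of == "mutation"
  if (any(mut) && !all(values[mut, , drop = FALSE] %in% c(0, 1)))
    stop("mutation-kind feature rows must contain only 0/1 values")
  dimnames(values) <- list(feature_ids, cell_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 gene_of = gene_of, kind_of = kind_of, cell_ids = cell_ids),
            class = "feature_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("sensitivity_matrix: %d drugs x %d cell lines (%.1f%% observed)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$observed_mask)))
  invisible(x)
}

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(factor(x$kind_of, levels = c("expression", "cnv", "mutation")))
  cat(sprintf("feature_matrix: %d features x %d cell lines (e=%d, n=%d, m=%d)\n",
              nrow(x$values), ncol(x$values), tab[1], tab[2], tab[3]))
  invisible(x)
}

# Column (cell line) subset, preserving class invariants.
subset_cells <- function(x, idx) {
  if (inherits(x, "sensitivity_matrix")) {
    sensitivity_matrix(x$values[, idx, drop = FALSE],
                       drug_ids = x$drug_ids, cell_ids = x$cell_ids[idx])
  } else if (inherits(x, "feature_matrix")) {
    feature_matrix(x$values[, idx, drop = FALSE],
                   feature_ids = x$feature_ids, gene_of = x$gene_of,
                   kind_of = x$kind_of, cell_ids = x$cell_ids[idx])
  } else stop("unsupported container")
}

# Align a feature matrix's cell lines to a sensitivity matrix's order.
align_cells <- function(Y, F) {
  stopifnot(inherits(Y, "sensitivity_matrix"), inherits(F, "feature_matrix"))
  if (identical(Y$cell_ids, F$cell_ids)) return(F)
  idx <- match(Y$cell_ids, F$cell_ids)
  if (anyNA(idx))
    stop("cell lines missing from feature matrix: ",
         paste(utils::head(Y$cell_ids[is.na(idx)], 5), collapse = ", "))
  subset_cells(F, idx)
}
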