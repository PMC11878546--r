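#' Normalized mutant-cell frequency per cell type
#'
#' For cell types `i` and mutations `j`, `N_ij` counts the cells of type `i`
#' carrying mutation `j`; each column is normalized by the mutation's total
#' mutant count `T_j`, giving `F_ij = N_ij / T_j` (columns sum to one).
#' Mutations with no mutant cells are dropped.
#'
#' @param mset a `mutation_set` from [call_mutations()].
#' @param type_labels character/factor of cell types, named by barcode or
#'   one per called cell; an unlabeled called cell is an error listing the
#'   barcodes.
#' @return a `celltype_freq`: list with matrices `N` (types x mutations),
#'   `F` (normalized) and vector `T` (total mutant cells per mutation).
#' @export
celltype_frequency <- function(mset, type_labels) {
  stopifnot(inherits(mset, "mutation_set"))
  type_labels <- match_labels(type_labels, colnames(mset$flags))
  type_labels <- as.factor(type_labels)
  N <- t(vapply(levels(type_labels), function(tp) {
    rowSums(mset$flags[, type_labels == tp, drop = FALSE])
  }, numeric(nrow(mset$flags))))
  colnames(N) <- mset$mutations$locus
  Tj <- colSums(N)
  keep <- Tj > 0
  N <- N[, keep, drop = FALSE]
  Tj <- Tj[keep]
  F_mat <- sweep(N, 2L, Tj, "/")
  structure(list(N = N, F = F_mat, T = Tj), class = "celltype_freq")
}

#' Cluster cell types by their mutation frequency profiles
#'
#' Complete-linkage hierarchical clustering on the Euclidean distances
#' between the rows of the normalized frequency matrix `F`: cell types that
#' share mutations in similar proportions merge early, recovering lineage
#' relationships (e.g. the two lymphoid types joining before the myeloid
#' one).
#'
#' @param freq a [celltype_frequency()] result.
#' @return an [stats::hclust] tree (for a single cell type, a trivial
#'   degenerate list with the one label).
#' @export
cluster_celltypes <- function(freq) {
  stopifnot(inherits(freq, "celltype_freq"))
  if (ncol(freq$F) < 1L) stop("at least one mutation is required")
  if (nrow(freq$F) < 2L) {
    return(structure(list(labels = rownames(freq$F), trivial = TRUE),
                     class = "trivial_tree"))
  }
  stats::hclust(stats::dist(freq$F, method = "euclidean"), method = "complete")
}

#' Staircase ordering for mutation heatmaps
#'
#' Orders a binary mutations x cells matrix the way clonal heatmaps are
#' drawn: rows (mutations) by decreasing mutant-cell count, then columns
#' (cells) by treating each cell's membership vector in that row order as a
#' binary number, descending. Cells carrying the top mutation come first,
#' within them cells also carrying the second, and so on, producing
#' contiguous staircase blocks for nested clones. Ties keep the original
#' order, so cells with no mutation stay rightmost in input order and the
#' ordering is idempotent.
#'
#' @param binary_matrix logical or 0/1 matrix, mutations x cells.
#' @return list with `row_order`, `col_order` (integer permutations) and
#'   `sorted` (the reordered matrix).
#' @export
memo_sort <- function(binary_matrix) {
  mat <- as.matrix(binary_matrix) * 1
  if (any(!mat %in% c(0, 1))) stop("matrix must be binary")
  row_order <- order(-rowSums(mat), seq_len(nrow(mat)), method = "radix")
  if (nrow(mat)) {
    keys <- lapply(row_order, function(r) -mat[r, ])
    col_order <- do.call(order, c(keys, list(seq_len(ncol(mat)), method = "radix")))
  } else {
    col_order <- seq_len(ncol(mat))
  }
  list(row_order = row_order, col_order = col_order,
       sorted = mat[row_order, col_order, drop = FALSE])
}
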