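#' Allele count tensor
#'
#' The sole input of the statistical core: read counts `n(x, i, j)` for each
#' base `x` in A/C/G/T, cell `i` and locus `j`, stored as four sparse
#' loci-by-cells matrices. The per cell-and-locus sequencing depth is
#' `N(i, j) = n(A,i,j) + n(T,i,j) + n(C,i,j) + n(G,i,j)`.
#'
#' @param counts named list of four integer matrices (`A`, `C`, `G`, `T`),
#'   each loci x cells; dense matrices are converted to sparse.
#' @param loci data.frame with columns `contig` (character) and `pos`
#'   (1-based integer position); rows must be unique.
#' @param cells character vector of unique cell barcodes (one per column).
#'
#' @return an object of class `allele_count_tensor` with elements `counts`
#'   (list of four `dgCMatrix`), `loci`, `cells` and `zero_coverage` (logical
#'   per-locus flag for loci with no reads in any cell).
#' @export
allele_count_tensor <- function(counts, loci, cells) {
  if (!is.list(counts) || !setequal(names(counts), BASES)) {
    stop("`counts` must be a named list with elements A, C, G, T")
  }
  cells <- as.character(cells)
  if (anyDuplicated(cells)) stop("cell barcodes must be unique")
  loci <- as.data.frame(loci)
  if (!all(c("contig", "pos") %in% names(loci))) {
    stop("`loci` must have columns contig and pos")
  }
  loci$contig <- as.character(loci$contig)
  loci$pos <- as.integer(loci$pos)
  if (anyDuplicated(loci[c("contig", "pos")])) stop("loci must be unique")
  ord <- order(loci$contig, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  dn <- list(locus_names(loci), cells)
  counts <- lapply(counts[BASES], function(x) {
    x <- methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"), "dMatrix")
    if (nrow(x) != nrow(loci) || ncol(x) != length(cells)) {
      stop("count matrices must be loci x cells")
    }
    v <- x@x
    if (length(v) && (any(v < 0) || any(v != round(v)))) {
      stop("counts must be non-negative integers")
    }
    x <- x[ord, , drop = FALSE]
    dimnames(x) <- dn
    x
  })
  depth_rows <- Matrix::rowSums(counts$A + counts$C + counts$G + counts$T)
  structure(
    list(counts = counts, loci = loci, cells = cells,
         zero_coverage = unname(depth_rows == 0)),
    class = "allele_count_tensor"
  )
}

BASES <- c("A", "C", "G", "T")

#' Locus names in `contig.pos` form (e.g. `chrM.310`)
#' @param loci data.frame with `contig` and `pos` columns.
#' @return character vector.
#' @export
locus_names <- function(loci) paste(loci$contig, loci$pos, sep = ".")

#' @export
dim.allele_count_tensor <- function(x) c(nrow(x$loci), length(x$cells))

#' @export
print.allele_count_tensor <- function(x, ...) {
  cat(sprintf("allele_count_tensor: %d loci x %d cells (%d zero-coverage loci)\n",
              nrow(x$loci), length(x$cells), sum(x$zero_coverage)))
  invisible(x)
}

#' Subset a tensor by cells and/or loci
#'
#' @param tensor an `allele_count_tensor`.
#' @param cells character vector of barcodes to keep (default all).
#' @param loci integer or logical index into the locus table (default all).
#' @return a new `allele_count_tensor`.
#' @export
tensor_subset <- function(tensor, cells = tensor$cells, loci = seq_len(nrow(tensor$loci))) {
  stopifnot(inherits(tensor, "allele_count_tensor"))
  ci <- match(cells, tensor$cells)
  if (anyNA(ci)) stop("unknown barcodes: ", paste(cells[is.na(ci)], collapse = ", "))
  allele_count_tensor(
    lapply(tensor$counts, function(m) m[loci, ci, drop = FALSE]),
    tensor$loci[loci, , drop = FALSE],
    tensor$cells[ci]
  )
}

#' Sequencing depth per cell and locus
#'
#' Elementwise sum of the four per-base count matrices.
#'
#' @param tensor an `allele_count_tensor`.
#' @return sparse loci x cells matrix of depths `N(i, j)`.
#' @export
compute_depth <- function(tensor) {
  stopifnot(inherits(tensor, "allele_count_tensor"))
  with(tensor$counts, A + C + G + T)
}
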