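#' Reference-free wild-type allele per locus
#'
#' The wild-type (WT) allele of a locus is the base whose median raw count
#' across all cells is maximal, so no reference genome is needed and
#' individual polymorphisms relative to a reference do not register as
#' mutations. Ties between bases with equal maximal medians are broken by the
#' fixed order A < C < G < T and flagged.
#'
#' @param tensor an [allele_count_tensor()].
#' @param block number of loci per dense block when computing row medians of
#'   the sparse count matrices (memory/speed trade-off only).
#' @return a `wildtype_profile`: data.frame with one row per locus, columns
#'   `contig`, `pos`, `wt` (base), `tie` (logical), `zero_coverage`, and the
#'   per-base median counts `med_A`, `med_C`, `med_G`, `med_T`.
#' @export
call_wildtype <- function(tensor, block = 2048L) {
  stopifnot(inherits(tensor, "allele_count_tensor"))
  n_loci <- nrow(tensor$loci)
  if (length(tensor$cells) < 1L) stop("at least one cell is required")
  med <- matrix(0, n_loci, 4L, dimnames = list(NULL, BASES))
  for (start in seq(1L, n_loci, by = block)) {
    idx <- start:min(start + block - 1L, n_loci)
    for (b in BASES) {
      dense <- as.matrix(tensor$counts[[b]][idx, , drop = FALSE])
      med[idx, b] <- apply(dense, 1L, stats::median)
    }
  }
  best <- max.col(med, ties.method = "first")  # column order A,C,G,T
  n_max <- rowSums(med == med[cbind(seq_len(n_loci), best)])
  out <- data.frame(
    contig = tensor$loci$contig,
    pos = tensor$loci$pos,
    wt = BASES[best],
    tie = n_max > 1L,
    zero_coverage = tensor$zero_coverage,
    stringsAsFactors = FALSE
  )
  out[paste0("med_", BASES)] <- as.data.frame(med)
  class(out) <- c("wildtype_profile", "data.frame")
  out
}

#' Wild-type read counts and wild-type allele frequency
#'
#' For each cell and locus, `m(i, j)` is the count of the locus' WT base and
#' `wAF(i, j) = m / N` is the WT allele frequency, used as a proxy for the
#' WT heteroplasmy level. Cells with zero depth at a locus get a missing
#' (`NA`) wAF, never 0 or 1.
#'
#' @param tensor an [allele_count_tensor()].
#' @param profile a `wildtype_profile` computed on the same loci.
#' @return a `wt_read_table`: list with loci x cells matrices `m` (WT
#'   counts, sparse), `depth` (sparse) and `af` (dense, `NA` where depth 0).
#' @export
wt_reads <- function(tensor, profile) {
  stopifnot(inherits(tensor, "allele_count_tensor"), inherits(profile, "wildtype_profile"))
  if (nrow(profile) != nrow(tensor$loci) ||
      !all(profile$pos == tensor$loci$pos & profile$contig == tensor$loci$contig)) {
    stop("profile was not computed on the same loci")
  }
  m <- tensor$counts$A * 0
  for (b in BASES) {
    rows <- which(profile$wt == b)
    if (length(rows)) m[rows, ] <- tensor$counts[[b]][rows, , drop = FALSE]
  }
  depth <- compute_depth(tensor)
  af <- as.matrix(m) / as.matrix(depth)
  af[as.matrix(depth) == 0] <- NA_real_
  structure(list(m = m, depth = depth, af = af), class = "wt_read_table")
}

#' Select cells by mitochondrial depth
#'
#' Keeps cells whose per-cell depth statistic over all loci exceeds a
#' threshold; the default (mean depth > 5) is the quality filter applied to
#' every dataset before model fitting.
#'
#' @param tensor an [allele_count_tensor()].
#' @param min_mean_depth threshold; a cell is kept when its statistic is
#'   strictly greater.
#' @param stat `"mean"` (default) or `"median"` of the per-cell depths.
#' @return character vector of retained barcodes.
#' @export
filter_cells_by_depth <- function(tensor, min_mean_depth = 5, stat = c("mean", "median")) {
  stopifnot(inherits(tensor, "allele_count_tensor"))
  stat <- match.arg(stat)
  depth <- compute_depth(tensor)
  per_cell <- if (stat == "mean") {
    Matrix::colMeans(depth)
  } else {
    apply(as.matrix(depth), 2L, stats::median)
  }
  keep <- tensor$cells[per_cell > min_mean_depth]
  if (length(keep) == 0L) warning("no cell passes the depth filter")
  keep
}
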