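#' Read mgatk-style per-base count tables
#'
#' Reads the per-base allele count dialect written by mgatk-like pileup
#' tools: one (optionally gzipped) headerless CSV per base, with position,
#' barcode and forward/reverse strand counts per row, plus an optional
#' coverage table. Forward and reverse counts are summed on import (the
#' statistical core uses no strand information). Column order varies across
#' upstream versions, so it is configurable through `col_order`.
#'
#' @param dir directory containing `A.txt.gz`, `C.txt.gz`, `G.txt.gz`,
#'   `T.txt.gz` (a plain `.txt` fallback is accepted).
#' @param barcodes optional whitelist: a character vector, or path to a
#'   one-column TSV; barcodes present in the counts but absent from the
#'   whitelist are dropped (their number is reported via `message()`), and
#'   whitelisted barcodes missing from the counts appear as all-zero cells.
#' @param col_order names of the four columns in file order; a permutation
#'   of `c("pos", "barcode", "fwd", "rev")`.
#' @param contig contig name for all loci.
#' @return an [allele_count_tensor()].
#' @export
read_mgatk <- function(dir, barcodes = NULL,
                       col_order = c("pos", "barcode", "fwd", "rev"),
                       contig = "chrM") {
  if (!setequal(col_order, c("pos", "barcode", "fwd", "rev"))) {
    stop("col_order must be a permutation of pos, barcode, fwd, rev")
  }
  tabs <- lapply(BASES, function(b) {
    f <- file.path(dir, paste0(b, ".txt.gz"))
    if (!file.exists(f)) f <- file.path(dir, paste0(b, ".txt"))
    if (!file.exists(f)) {
      stop("missing base file: ", file.path(dir, paste0(b, ".txt.gz")))
    }
    read_base_table(f, col_order)
  })
  names(tabs) <- BASES

  if (!is.null(barcodes) && length(barcodes) == 1L && file.exists(barcodes)) {
    barcodes <- utils::read.table(barcodes, stringsAsFactors = FALSE)[[1]]
  }
  all_bc <- unique(unlist(lapply(tabs, `[[`, "barcode")))
  if (is.null(barcodes)) {
    cells <- sort(all_bc)
  } else {
    dropped <- setdiff(all_bc, barcodes)
    if (length(dropped)) {
      message(length(dropped), " barcode(s) absent from the whitelist were dropped")
    }
    cells <- barcodes
  }
  pos <- sort(unique(unlist(lapply(tabs, `[[`, "pos"))))
  loci <- data.frame(contig = contig, pos = pos, stringsAsFactors = FALSE)
  counts <- lapply(tabs, function(tb) {
    tb <- tb[tb$barcode %in% cells, , drop = FALSE]
    Matrix::sparseMatrix(i = match(tb$pos, pos), j = match(tb$barcode, cells),
                         x = tb$fwd + tb$rev,
                         dims = c(length(pos), length(cells)))
  })
  allele_count_tensor(counts, loci, cells)
}

read_base_table <- function(path, col_order) {
  tb <- tryCatch(
    utils::read.csv(path, header = FALSE, colClasses = "character"),
    error = function(e) stop("no records in ", path)
  )
  if (nrow(tb) == 0L) stop("no records in ", path)
  if (ncol(tb) != 4L) stop("malformed table ", path, ": expected 4 columns")
  names(tb) <- col_order
  for (col in c("pos", "fwd", "rev")) {
    v <- suppressWarnings(as.numeric(tb[[col]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop("malformed row in ", path, " at line ", bad[1],
           ": non-integer ", col, " value '", tb[[col]][bad[1]], "'")
    }
    tb[[col]] <- as.integer(v)
  }
  tb
}

#' Read cellSNP-lite-style sparse AD/DP matrices
#'
#' Maps the biallelic AD/DP dialect onto the four-base tensor: per variant
#' row, the REF base receives `DP - AD` reads, the ALT base `AD`, and the
#' remaining two bases zero. `AD > DP` anywhere is an error; variants with a
#' non-ACGT REF or ALT are skipped with a warning.
#'
#' @param ad_matrix,dp_matrix paths to Matrix Market files of identical
#'   shape (variants x cells).
#' @param variants path to a variant list: tab-separated `CHROM POS REF ALT`
#'   or VCF-style `CHROM POS ID REF ALT`; `#`-prefixed header lines ignored.
#' @param barcodes path to a one-column barcode file (one per matrix column).
#' @return an [allele_count_tensor()].
#' @export
read_cellsnp <- function(ad_matrix, dp_matrix, variants, barcodes) {
  ad <- methods::as(Matrix::readMM(ad_matrix), "CsparseMatrix")
  dp <- methods::as(Matrix::readMM(dp_matrix), "CsparseMatrix")
  if (!identical(dim(ad), dim(dp))) stop("AD and DP matrices differ in shape")
  if (any((dp - ad)@x < 0)) stop("AD exceeds DP for some entries")
  var_tab <- utils::read.table(variants, header = FALSE, comment.char = "#",
                               stringsAsFactors = FALSE)
  if (ncol(var_tab) >= 5L) var_tab <- var_tab[, c(1, 2, 4, 5)]
  if (ncol(var_tab) != 4L) stop("variant list must have 4 (or VCF-style 5+) columns")
  names(var_tab) <- c("contig", "pos", "ref", "alt")
  if (nrow(var_tab) != nrow(ad)) stop("variant list length does not match matrix rows")
  cells <- utils::read.table(barcodes, stringsAsFactors = FALSE)[[1]]
  if (length(cells) != ncol(ad)) stop("barcode list length does not match matrix columns")

  ok <- var_tab$ref %in% BASES & var_tab$alt %in% BASES
  if (!all(ok)) {
    warning(sum(!ok), " variant(s) with non-ACGT ref/alt skipped")
    var_tab <- var_tab[ok, , drop = FALSE]
    ad <- ad[ok, , drop = FALSE]; dp <- dp[ok, , drop = FALSE]
  }
  if (anyDuplicated(var_tab[c("contig", "pos")])) {
    stop("multi-allelic loci are not supported by the AD/DP dialect")
  }
  ref_counts <- dp - ad
  counts <- lapply(BASES, function(b) {
    out <- methods::as(ad * 0, "CsparseMatrix")
    r <- which(var_tab$ref == b)
    if (length(r)) out[r, ] <- ref_counts[r, , drop = FALSE]
    a <- which(var_tab$alt == b)
    if (length(a)) out[a, ] <- ad[a, , drop = FALSE]
    out
  })
  names(counts) <- BASES
  allele_count_tensor(counts, var_tab[c("contig", "pos")], cells)
}

#' Export result tables from a store
#'
#' Writes a TSV with loci as rows and cells as columns (`what = "qvalues"`
#' or `"af"`, missing values as empty fields), or the long-format calls
#' table (`what = "calls"`: cell, locus, p, q, mutant flag). A requested
#' stage that has not been computed yet is an error naming the pipeline
#' step to run.
#'
#' @param store a [store_open()] handle.
#' @param what one of `"qvalues"`, `"af"`, `"calls"`.
#' @param out output file path.
#' @return `out`, invisibly.
#' @export
export_results <- function(store, what = c("qvalues", "af", "calls"), out) {
  what <- match.arg(what)
  if (what == "calls") {
    tab <- store_read(store, "calls", "table", missing_hint = "run call_mutations() first")
    utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  } else {
    name <- if (what == "qvalues") "q" else "af"
    mat <- store_read(store, "pvals", name, missing_hint = "run fit_all_loci() first")
    utils::write.table(as.matrix(mat), out, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA, na = "")
  }
  invisible(out)
}
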