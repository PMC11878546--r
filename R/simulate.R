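#' Specification of the multi-allele collision simulation
#'
#' The mutation caller assumes at most one mutant allele per locus. To check
#' how often that assumption would fail, all possible single-nucleotide
#' mutation events on a 16 kb mitochondrial genome are enumerated
#' (16,000 loci x 3 alternative bases = 48,000 events) and a mutation set of
#' size `n_mutations` is drawn uniformly without replacement, many times.
#'
#' @param n_mutations number of mutations drawn per repetition.
#' @param repetitions number of repetitions.
#' @param genome_length number of loci (default 16,000).
#' @param alt_bases_per_locus alternative bases per locus (default 3).
#' @return a `collision_spec` with derived `event_count`.
#' @export
collision_spec <- function(n_mutations, repetitions = 100000L,
                           genome_length = 16000L, alt_bases_per_locus = 3L) {
  event_count <- as.integer(genome_length) * as.integer(alt_bases_per_locus)
  if (n_mutations > event_count) stop("n_mutations exceeds the number of possible events")
  stopifnot(n_mutations >= 1, repetitions >= 1)
  structure(list(n_mutations = as.integer(n_mutations),
                 repetitions = as.integer(repetitions),
                 genome_length = as.integer(genome_length),
                 alt_bases_per_locus = as.integer(alt_bases_per_locus),
                 event_count = event_count),
            class = "collision_spec")
}

#' Probability that a locus receives multiple mutant alleles
#'
#' Monte-Carlo estimate: per repetition, sample `n_mutations` events without
#' replacement and count loci hit by two or more distinct alternative
#' alleles; the probability is the total count of such loci across
#' repetitions divided by (mutations per repetition x repetitions). A
#' closed-form check for the expectation is `(k - 1) / (E - 1)` with `k`
#' mutations and `E` events, since each of the `k - 1` other events shares
#' a locus with a given event with probability `2 / (E - 1)` per pair.
#'
#' @param spec a [collision_spec()].
#' @param seed optional RNG seed.
#' @return the estimated probability (a single number).
#' @export
collision_probability <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "collision_spec"))
  if (!is.null(seed)) set.seed(seed)
  k <- spec$n_mutations
  total <- 0L
  for (r in seq_len(spec$repetitions)) {
    ev <- sample.int(spec$event_count, k)
    locus <- (ev - 1L) %/% spec$alt_bases_per_locus
    total <- total + length(unique(locus[duplicated(locus)]))
  }
  total / (as.numeric(k) * spec$repetitions)
}

#' Specification of a synthetic clone dataset
#'
#' Generates data with exactly the structure the statistical model assumes:
#' each cell's WT heteroplasmy at a locus is Beta-distributed around the
#' locus baseline (mean `baseline_theta`, precision `precision = alpha+beta`),
#' depth follows a log-normal law rounded up to the nearest integer, and the
#' WT read count is binomial. Cells of a planted mutant clone have their WT
#' heteroplasmy at the planted locus replaced by `1 - het`. Reads not
#' carrying the WT base are assigned to one fixed alternative base per
#' locus, matching the one-mutation-per-locus assumption.
#'
#' @param n_cells number of cells.
#' @param n_loci number of loci.
#' @param baseline_theta mean WT heteroplasmy of unaffected cells (scalar or
#'   per-locus vector).
#' @param precision beta precision `alpha + beta` of the heteroplasmy law.
#' @param depth_meanlog,depth_sdlog log-normal depth parameters (defaults 2
#'   and 1, the law used for the model-recovery benchmarks).
#' @param clones character/factor of clone labels, one per cell (default one
#'   clone `"c0"`).
#' @param planted data.frame with columns `locus` (integer index), `clone`
#'   (label) and `het` (mutant heteroplasmy, i.e. the mutant allele fraction
#'   in mutant cells); may be empty.
#' @param seed RNG seed; the same spec always generates the same dataset.
#' @return a `clone_sim_spec`.
#' @export
clone_sim_spec <- function(n_cells = 200L, n_loci = 30L, baseline_theta = 0.999,
                           precision = 100, depth_meanlog = 2, depth_sdlog = 1,
                           clones = rep("c0", n_cells),
                           planted = data.frame(locus = integer(), clone = character(),
                                                het = numeric()),
                           seed = 1L) {
  stopifnot(all(baseline_theta > 0 & baseline_theta < 1), precision > 0,
            length(clones) == n_cells)
  planted <- as.data.frame(planted)
  if (nrow(planted)) {
    stopifnot(all(planted$locus >= 1 & planted$locus <= n_loci),
              all(planted$het > 0 & planted$het < 1),
              all(planted$clone %in% clones))
  }
  structure(list(n_cells = as.integer(n_cells), n_loci = as.integer(n_loci),
                 baseline_theta = rep_len(baseline_theta, n_loci),
                 precision = precision, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog, clones = as.character(clones),
                 planted = planted, seed = as.integer(seed)),
            class = "clone_sim_spec")
}

#' Generate a synthetic allele count tensor with known truth
#'
#' @param spec a [clone_sim_spec()].
#' @return list with `tensor` (an [allele_count_tensor()]) and `truth`
#'   (clone labels per cell, the planted mutation table with locus names,
#'   and the per-locus WT/alt bases).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "clone_sim_spec"))
  set.seed(spec$seed)
  S <- spec$n_cells; K <- spec$n_loci
  cells <- sprintf("cell%04d", seq_len(S))
  loci <- data.frame(contig = "chrM", pos = 100L + 10L * seq_len(K),
                     stringsAsFactors = FALSE)
  wt_base <- BASES[(seq_len(K) - 1L) %% 4L + 1L]
  alt_base <- BASES[seq_len(K) %% 4L + 1L]

  theta <- matrix(rep(spec$baseline_theta, each = S), nrow = K, ncol = S, byrow = TRUE)
  if (nrow(spec$planted)) {
    for (r in seq_len(nrow(spec$planted))) {
      mut_cells <- spec$clones == spec$planted$clone[r]
      theta[spec$planted$locus[r], mut_cells] <- 1 - spec$planted$het[r]
    }
  }
  s <- spec$precision
  pi <- matrix(stats::rbeta(K * S, theta * s, (1 - theta) * s), K, S)
  depth <- matrix(ceiling(stats::rlnorm(K * S, spec$depth_meanlog, spec$depth_sdlog)), K, S)
  m <- matrix(stats::rbinom(K * S, depth, pi), K, S)

  counts <- lapply(BASES, function(b) {
    out <- matrix(0L, K, S)
    wr <- which(wt_base == b)
    if (length(wr)) out[wr, ] <- m[wr, , drop = FALSE]
    ar <- which(alt_base == b)
    if (length(ar)) out[ar, ] <- depth[ar, , drop = FALSE] - m[ar, , drop = FALSE]
    out
  })
  names(counts) <- BASES
  tensor <- allele_count_tensor(counts, loci, cells)
  planted <- spec$planted
  if (nrow(planted)) {
    planted$locus_name <- locus_names(loci)[planted$locus]
  } else {
    planted$locus_name <- character(0)
  }
  list(tensor = tensor,
       truth = list(clones = stats::setNames(spec$clones, cells),
                    planted = planted,
                    wt_base = wt_base, alt_base = alt_base))
}

#' Write a tensor out in an upstream count dialect
#'
#' Emits either the per-base mgatk-style tables (strand counts split 50/50,
#' remainder to the forward strand, plus `coverage.txt.gz`) or the
#' cellSNP-lite-style AD/DP Matrix Market pair with variant and barcode
#' lists. The AD/DP dialect is biallelic: loci carrying reads on more than
#' two bases are an error.
#'
#' @param tensor an [allele_count_tensor()].
#' @param dialect `"mgatk"` or `"cellsnp"`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(tensor, dialect = c("mgatk", "cellsnp"), out_dir) {
  stopifnot(inherits(tensor, "allele_count_tensor"))
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (dialect == "mgatk") {
    for (b in BASES) {
      mat <- as.matrix(tensor$counts[[b]])
      idx <- which(mat > 0, arr.ind = TRUE)
      n <- mat[idx]
      tb <- data.frame(pos = tensor$loci$pos[idx[, 1]],
                       barcode = tensor$cells[idx[, 2]],
                       fwd = ceiling(n / 2), rev = floor(n / 2))
      con <- gzfile(file.path(out_dir, paste0(b, ".txt.gz")), "w")
      utils::write.table(tb, con, sep = ",", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      close(con)
    }
    depth <- as.matrix(compute_depth(tensor))
    idx <- which(depth > 0, arr.ind = TRUE)
    cov <- data.frame(pos = tensor$loci$pos[idx[, 1]],
                      barcode = tensor$cells[idx[, 2]],
                      coverage = depth[idx])
    con <- gzfile(file.path(out_dir, "coverage.txt.gz"), "w")
    utils::write.table(cov, con, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  } else {
    totals <- vapply(tensor$counts, Matrix::rowSums, numeric(nrow(tensor$loci)))
    if (nrow(tensor$loci) == 1L) totals <- matrix(totals, nrow = 1, dimnames = list(NULL, BASES))
    n_bases <- rowSums(totals > 0)
    if (any(n_bases > 2L)) {
      stop("the AD/DP dialect is biallelic; loci with >2 observed bases: ",
           paste(locus_names(tensor$loci)[n_bases > 2L], collapse = ", "))
    }
    ref <- BASES[max.col(totals, ties.method = "first")]
    alt <- vapply(seq_len(nrow(totals)), function(j) {
      others <- BASES[totals[j, ] > 0 & BASES != ref[j]]
      if (length(others)) others[1] else setdiff(BASES, ref[j])[1]
    }, "")
    dp <- compute_depth(tensor)
    ad <- dp * 0
    for (b in BASES) {
      rows <- which(alt == b)
      if (length(rows)) ad[rows, ] <- tensor$counts[[b]][rows, , drop = FALSE]
    }
    Matrix::writeMM(methods::as(ad, "CsparseMatrix"), file.path(out_dir, "cellSNP.tag.AD.mtx"))
    Matrix::writeMM(methods::as(dp, "CsparseMatrix"), file.path(out_dir, "cellSNP.tag.DP.mtx"))
    utils::write.table(data.frame(tensor$loci$contig, tensor$loci$pos, ref, alt),
                       file.path(out_dir, "cellSNP.variants.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(tensor$cells, file.path(out_dir, "cellSNP.samples.tsv"))
  }
  invisible(out_dir)
}
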