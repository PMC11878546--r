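#' Call mutations from a q-value table
#'
#' A locus is reported as a lineage-informative mutation when at least
#' `min_mutant_cells` cells have a q-value below `q_threshold` (defaults
#' 5 and 0.01). The per-cell mutant flags of a reported locus are exactly
#' the cells counted toward the threshold.
#'
#' @param calls a `mito_calls` object from [fit_all_loci()], or a
#'   [store_open()] handle holding a persisted q matrix (so calls can be
#'   re-made with new thresholds without refitting).
#' @param config a [calling_config()]; only `q_threshold` and
#'   `min_mutant_cells` are used here.
#' @param store optional store handle; the call table is persisted under
#'   `calls` when given.
#' @return a `mutation_set`: list with `mutations` (data.frame: `locus`,
#'   `n_mutant` = clone size), `flags` (logical mutations x cells matrix)
#'   and `table` (long data.frame `cell`, `locus`, `p`, `q`, `mutant` over
#'   all cells of reported mutations).
#' @export
call_mutations <- function(calls, config = calling_config(), store = NULL) {
  if (inherits(calls, "store_handle")) {
    st <- calls
    q <- store_read(st, "pvals", "q", missing_hint = "run fit_all_loci() first")
    p <- store_read(st, "pvals", "p", missing_hint = "run fit_all_loci() first")
  } else {
    stopifnot(inherits(calls, "mito_calls"))
    q <- calls$q; p <- calls$p
  }
  mut_cell <- !is.na(q) & q < config$q_threshold
  n_mut <- rowSums(mut_cell)
  rep_loci <- which(n_mut >= config$min_mutant_cells)
  flags <- mut_cell[rep_loci, , drop = FALSE]
  mutations <- data.frame(locus = rownames(q)[rep_loci],
                          n_mutant = unname(n_mut[rep_loci]),
                          stringsAsFactors = FALSE)
  if (length(rep_loci)) {
    tab <- data.frame(
      cell = rep(colnames(q), each = length(rep_loci)),
      locus = rep(rownames(q)[rep_loci], times = ncol(q)),
      p = as.vector(p[rep_loci, , drop = FALSE]),
      q = as.vector(q[rep_loci, , drop = FALSE]),
      mutant = as.vector(flags),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- data.frame(cell = character(), locus = character(),
                      p = numeric(), q = numeric(), mutant = logical(),
                      stringsAsFactors = FALSE)
  }
  out <- structure(list(mutations = mutations, flags = flags, table = tab,
                        config = config),
                   class = "mutation_set")
  if (!is.null(store)) {
    store_write(store, "calls", "table", tab,
                attrs = list(q_threshold = config$q_threshold,
                             min_mutant_cells = config$min_mutant_cells))
    store_write(store, "calls", "mutations", mutations)
  }
  out
}

#' @export
print.mutation_set <- function(x, ...) {
  cat(sprintf("mutation_set: %d mutations (q < %g, >= %d mutant cells)\n",
              nrow(x$mutations), x$config$q_threshold, x$config$min_mutant_cells))
  invisible(x)
}

#' Per-mutation precision against a ground-truth cell subset
#'
#' For each reported mutation with at least one mutant cell in the target
#' subset, precision is the fraction of its mutant cells that belong to the
#' subset, `y_i = n_i / m_i`; the overall precision is the ratio of summed
#' numerators to summed denominators (not the mean of the per-mutation
#' values).
#'
#' @param mset a `mutation_set`.
#' @param labels logical vector (or named logical covering all called cells):
#'   `TRUE` for cells in the ground-truth subset.
#' @return a `precision_report`: list with `per_mutation` (data.frame
#'   `locus`, `n_in_subset`, `clone_size`, `precision`) and `overall`.
#' @export
mutation_precision <- function(mset, labels) {
  stopifnot(inherits(mset, "mutation_set"))
  labels <- match_labels(labels, colnames(mset$flags))
  if (!is.logical(labels)) stop("`labels` must be logical subset membership")
  n_i <- as.vector(mset$flags %*% as.numeric(labels))
  m_i <- rowSums(mset$flags)
  keep <- n_i > 0 & m_i > 0
  per <- data.frame(locus = mset$mutations$locus[keep],
                    n_in_subset = n_i[keep], clone_size = m_i[keep],
                    precision = n_i[keep] / m_i[keep],
                    stringsAsFactors = FALSE)
  structure(list(per_mutation = per,
                 overall = if (any(keep)) sum(n_i[keep]) / sum(m_i[keep]) else NA_real_),
            class = "precision_report")
}

#' Per-mutation lineage precision for two lineages
#'
#' With binary lineage labels (e.g. epithelial vs blood), each mutation's
#' lineage precision is the fraction of its mutant cells that lie in its
#' dominant lineage, `max(n_i, m_i) / (n_i + m_i)`, a value in [0.5, 1];
#' 1 means the mutation is confined to one lineage. Mutations with no
#' called cells are excluded.
#'
#' @param mset a `mutation_set`.
#' @param lineage_labels factor/character of exactly two levels, or logical,
#'   one per called cell (named vectors are matched by barcode).
#' @return a `precision_report` with `per_mutation` columns `locus`,
#'   `n_lineage1`, `n_lineage2`, `precision`, and `overall` computed on the
#'   pooled counts.
#' @export
lineage_precision <- function(mset, lineage_labels) {
  stopifnot(inherits(mset, "mutation_set"))
  lab <- match_labels(lineage_labels, colnames(mset$flags))
  if (!is.logical(lab)) {
    lab <- as.factor(lab)
    if (nlevels(lab) != 2L) stop("lineage labels must be binary")
    lab <- lab == levels(lab)[1]
  }
  n1 <- as.vector(mset$flags %*% as.numeric(lab))
  n2 <- rowSums(mset$flags) - n1
  keep <- (n1 + n2) > 0
  per <- data.frame(locus = mset$mutations$locus[keep],
                    n_lineage1 = n1[keep], n_lineage2 = n2[keep],
                    precision = pmax(n1[keep], n2[keep]) / (n1[keep] + n2[keep]),
                    stringsAsFactors = FALSE)
  structure(list(per_mutation = per,
                 overall = if (any(keep)) sum(pmax(n1[keep], n2[keep])) / sum(n1[keep] + n2[keep]) else NA_real_),
            class = "precision_report")
}

match_labels <- function(labels, cells) {
  if (!is.null(names(labels))) {
    miss <- setdiff(cells, names(labels))
    if (length(miss)) stop("cells without a label: ", paste(miss, collapse = ", "))
    labels <- labels[cells]
  } else if (length(labels) != length(cells)) {
    stop("labels must be named by barcode or have one entry per called cell")
  }
  labels
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("precision_report: %d mutations, overall precision %.3f\n",
              nrow(x$per_mutation), x$overall))
  invisible(x)
}
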