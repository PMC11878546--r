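#' Calling configuration
#'
#' Default thresholds used throughout: mutation q-value below 0.01, at least
#' 5 mutant cells per reported mutation, per-cell mean mitochondrial depth
#' above 5, and a 0.05 FDR threshold for the binomial-mixture WT-cell
#' classifier. All of them can be changed; for sparse multiome data a higher
#' `min_mutant_cells` (e.g. 10) is a config change, not a separate mode.
#'
#' @param q_threshold mutation q-value threshold (cells with `q < q_threshold`
#'   count as mutant).
#' @param min_mutant_cells minimum number of mutant cells for a locus to be
#'   reported as a mutation.
#' @param min_mean_depth per-cell depth filter threshold (strictly greater).
#' @param depth_stat per-cell depth statistic, `"mean"` or `"median"`.
#' @param classifier_fdr adjusted-P threshold of the WT-cell preselection.
#' @param preselect logical; disable to fit the null on all depth-passing cells.
#' @return a `calling_config` list.
#' @export
calling_config <- function(q_threshold = 0.01, min_mutant_cells = 5L,
                           min_mean_depth = 5, depth_stat = c("mean", "median"),
                           classifier_fdr = 0.05, preselect = TRUE) {
  depth_stat <- match.arg(depth_stat)
  stopifnot(q_threshold > 0, q_threshold <= 1,
            min_mutant_cells >= 1, min_mean_depth >= 0,
            classifier_fdr >= 0, classifier_fdr <= 1,
            is.logical(preselect))
  structure(list(q_threshold = q_threshold,
                 min_mutant_cells = as.integer(min_mutant_cells),
                 min_mean_depth = min_mean_depth, depth_stat = depth_stat,
                 classifier_fdr = classifier_fdr, preselect = preselect),
            class = "calling_config")
}

#' Fit every locus and compute per-cell mutation q-values
#'
#' Runs the full statistical core over all loci of a tensor: depth-filters
#' cells, determines the WT allele per locus, fits the binomial mixture and
#' preselects WT reference cells, fits the beta-binomial null on those cells,
#' and converts each cell's lower-tail probability into a per-locus BH
#' q-value. Loci whose fit fails (e.g. fewer than two usable cells) are
#' flagged and skipped; the pipeline continues.
#'
#' Fitting is deterministic, so results are identical for any `cores` value.
#'
#' @param tensor an [allele_count_tensor()].
#' @param profile optional precomputed [call_wildtype()] profile; the WT
#'   allele is always defined on all imported cells, while the depth filter
#'   applies only to fitting and calling.
#' @param config a [calling_config()].
#' @param cores parallel degree for the per-locus loop (forked workers).
#' @param store optional [store_open()] handle; when given, counts, profile,
#'   fits and p/q matrices are persisted under their groups.
#' @return a `mito_calls` object: list with dense loci x kept-cells matrices
#'   `p`, `q`, `af`, `depth`, the per-locus data.frames `bm` and `bb`, the
#'   logical WT `selection` matrix, `profile`, `config`, `cells`.
#' @export
fit_all_loci <- function(tensor, profile = NULL, config = calling_config(),
                         cores = 1L, store = NULL) {
  stopifnot(inherits(tensor, "allele_count_tensor"), inherits(config, "calling_config"))
  cells_keep <- filter_cells_by_depth(tensor, config$min_mean_depth, config$depth_stat)
  if (is.null(profile)) profile <- call_wildtype(tensor)
  wt <- wt_reads(tensor, profile)
  ci <- match(cells_keep, tensor$cells)
  m_all <- as.matrix(wt$m)[, ci, drop = FALSE]
  n_all <- as.matrix(wt$depth)[, ci, drop = FALSE]
  af_all <- wt$af[, ci, drop = FALSE]
  n_loci <- nrow(tensor$loci)

  fit_one <- function(j) {
    mj <- m_all[j, ]; nj <- n_all[j, ]
    res <- list(p = rep(NA_real_, length(mj)), q = rep(NA_real_, length(mj)),
                selected = rep(NA, length(mj)),
                bm = c(pi_w = NA_real_, pi_m = NA_real_, theta_w = NA_real_),
                bb = c(alpha = NA_real_, beta = NA_real_, theta = NA_real_,
                       phi = NA_real_, loglik = NA_real_, n_cells = NA_real_),
                status = "ok")
    if (sum(nj > 0) < 2L) { res$status <- "too_few_cells"; return(res) }
    out <- tryCatch({
      bm <- fit_binomial_mixture(mj, nj)
      pbm <- p_bmd(mj, nj, bm)
      sel <- withCallingHandlers(
        select_wt_cells(pbm, config$classifier_fdr, config$preselect),
        warning = function(w) invokeRestart("muffleWarning")
      )
      bb <- fit_betabinom(mj[sel$selected], nj[sel$selected])
      p <- bbd_lower_tail(mj, nj, bb)
      list(bm = bm, sel = sel, bb = bb, p = p)
    }, error = function(e) e)
    if (inherits(out, "error")) { res$status <- conditionMessage(out); return(res) }
    res$p <- out$p
    res$q <- compute_qvalues(out$p)
    res$selected <- out$sel$selected
    res$bm <- c(pi_w = out$bm$pi_w, pi_m = out$bm$pi_m, theta_w = out$bm$theta_w)
    res$bb <- c(alpha = out$bb$alpha, beta = out$bb$beta, theta = out$bb$theta,
                phi = out$bb$phi, loglik = out$bb$loglik, n_cells = out$bb$n_cells)
    res
  }

  fits <- if (cores > 1L) {
    parallel::mclapply(seq_len(n_loci), fit_one, mc.cores = cores, mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n_loci), fit_one)
  }

  ln <- locus_names(tensor$loci)
  dn <- list(ln, cells_keep)
  grab <- function(field) {
    mat <- do.call(rbind, lapply(fits, `[[`, field))
    dimnames(mat) <- dn
    mat
  }
  bm <- as.data.frame(do.call(rbind, lapply(fits, `[[`, "bm")))
  bb <- as.data.frame(do.call(rbind, lapply(fits, `[[`, "bb")))
  bm$status <- bb$status <- vapply(fits, `[[`, "", "status")
  rownames(bm) <- rownames(bb) <- ln

  calls <- structure(list(p = grab("p"), q = grab("q"), af = af_all,
                          depth = n_all, selection = grab("selected"),
                          bm = bm, bb = bb, profile = profile,
                          config = config, cells = cells_keep),
                     class = "mito_calls")
  if (!is.null(store)) {
    ver <- as.character(utils::packageVersion("mitocall"))
    store_write(store, "counts", "tensor", tensor, attrs = list(tool_version = ver))
    store_write(store, "wildtype", "profile", profile)
    store_write(store, "bm_fit", "params", bm,
                attrs = list(classifier_fdr = config$classifier_fdr,
                             preselect = config$preselect))
    store_write(store, "bm_fit", "selection", calls$selection)
    store_write(store, "bb_fit", "params", bb)
    store_write(store, "pvals", "p", calls$p)
    store_write(store, "pvals", "q", calls$q)
    store_write(store, "pvals", "af", calls$af)
    store_write(store, "pvals", "config", config, attrs = unclass(config))
  }
  calls
}

#' @export
print.mito_calls <- function(x, ...) {
  cat(sprintf("mito_calls: %d loci x %d cells; %d loci fitted\n",
              nrow(x$q), ncol(x$q), sum(x$bb$status == "ok")))
  invisible(x)
}
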