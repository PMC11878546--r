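#' Two-component binomial mixture fitted by EM
#'
#' Models the WT allele count at one locus as a mixture of two binomials:
#' a WT cell population with WT-allele heteroplasmy `pi_w` and a mutant
#' population with heteroplasmy `pi_m`, in proportions `theta_w + theta_m = 1`.
#' The mixture is deliberately simple (no within-population heteroplasmy
#' variation) so it resists overfitting; it is used to preselect likely-WT
#' reference cells before the beta-binomial null is fitted.
#'
#' EM starts from component probabilities at the 10th and 90th percentiles of
#' the observed wAF with equal weights, and stops when the relative change in
#' log-likelihood falls below `tol`. Components are relabeled so the WT
#' component is the one with the larger success probability.
#'
#' @param m integer WT allele counts, one per cell.
#' @param N integer depths, same length; cells with `N = 0` are dropped.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return a `binomial_mixture_fit`: list with `pi_w`, `pi_m`, `theta_w`,
#'   `theta_m`, `loglik`, `loglik_trace`, `iterations`, `converged`,
#'   `degenerate`, `n_cells`.
#' @export
fit_binomial_mixture <- function(m, N, max_iter = 500L, tol = 1e-8) {
  stopifnot(length(m) == length(N))
  keep <- which(N > 0)
  m <- as.numeric(m[keep]); N <- as.numeric(N[keep])
  if (length(m) < 2L) stop("need at least 2 cells with positive depth")
  if (any(m < 0) || any(m > N)) stop("counts must satisfy 0 <= m <= N")
  af <- m / N

  mk <- function(pi_w, pi_m, theta_w, ll, trace, it, conv, degen) {
    structure(list(pi_w = pi_w, pi_m = pi_m, theta_w = theta_w,
                   theta_m = 1 - theta_w, loglik = ll, loglik_trace = trace,
                   iterations = it, converged = conv, degenerate = degen,
                   n_cells = length(m)),
              class = "binomial_mixture_fit")
  }

  # no variation at all (e.g. every cell saturated with m = N): a one-point
  # fit; pi_w = pi_m = common wAF, all weight on the WT component
  if (length(unique(af)) == 1L) {
    p <- af[1]
    ll <- sum(stats::dbinom(m, N, p, log = TRUE))
    return(mk(p, p, 1, ll, ll, 0L, TRUE, TRUE))
  }

  p1 <- stats::quantile(af, 0.9, names = FALSE)  # WT-leaning start
  p2 <- stats::quantile(af, 0.1, names = FALSE)
  if (p1 - p2 < 1e-6) {
    # skewed data: both percentiles coincide and EM would start on a
    # symmetric saddle; start the second component at the centre of the
    # below-maximum wAF values instead
    lower <- af[af < max(af)]
    p2 <- if (length(lower)) mean(lower) else p1 / 2
  }
  w1 <- 0.5
  trace <- numeric(0)
  ll_old <- -Inf
  conv <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    l1 <- log(w1) + stats::dbinom(m, N, p1, log = TRUE)
    l2 <- log(1 - w1) + stats::dbinom(m, N, p2, log = TRUE)
    mx <- pmax(l1, l2)
    bad <- !is.finite(mx)
    if (any(bad)) {
      # both components give zero mass (degenerate p at 0/1): nudge inward
      p1 <- min(max(p1, 1e-12), 1 - 1e-12)
      p2 <- min(max(p2, 1e-12), 1 - 1e-12)
      l1 <- log(w1) + stats::dbinom(m, N, p1, log = TRUE)
      l2 <- log(1 - w1) + stats::dbinom(m, N, p2, log = TRUE)
      mx <- pmax(l1, l2)
    }
    lse <- mx + log(exp(l1 - mx) + exp(l2 - mx))
    ll <- sum(lse)
    trace <- c(trace, ll)
    r1 <- exp(l1 - lse)                       # E step: WT responsibilities
    w1 <- mean(r1)                            # M step
    if (w1 > 0) p1 <- sum(r1 * m) / sum(r1 * N)
    if (w1 < 1) p2 <- sum((1 - r1) * m) / sum((1 - r1) * N)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) { conv <- TRUE; break }
    if (it >= max_iter) break
    ll_old <- ll
  }
  if (p1 >= p2) mk(p1, p2, w1, ll, trace, it, conv, FALSE)
  else          mk(p2, p1, 1 - w1, ll, trace, it, conv, FALSE)
}

#' Lower-tail probability under the WT mixture component
#'
#' `P(X <= m | N, pi_w)`: the probability, under the WT component of a fitted
#' binomial mixture, of observing at most the cell's WT allele count. Small
#' values mark cells that look mutant and should be excluded from the
#' beta-binomial reference set. The tail is inclusive of the observation.
#'
#' @param m WT allele count(s).
#' @param N depth(s); `N = 0` yields `NA` (probability undefined).
#' @param fit a `binomial_mixture_fit`.
#' @return probability vector in `[0, 1]` with `NA` at zero depth.
#' @export
p_bmd <- function(m, N, fit) {
  stopifnot(inherits(fit, "binomial_mixture_fit"))
  if (any(m < 0 | m > N, na.rm = TRUE)) stop("need 0 <= m <= N")
  out <- stats::pbinom(m, N, fit$pi_w)
  out[N == 0] <- NA_real_
  out
}

#' Preselect wild-type reference cells
#'
#' Benjamini-Hochberg adjusts the per-cell WT-component tail probabilities
#' across the cells of one locus and keeps cells whose adjusted value exceeds
#' `fdr_threshold` (default 0.05) as the WT reference set. With
#' `preselect = FALSE` every depth-passing cell is kept. If fewer than two
#' cells survive, all cells are kept with a warning, since the beta-binomial
#' fit would otherwise be degenerate.
#'
#' @param pvals per-cell `P_BMD` values at one locus (`NA` = no depth).
#' @param fdr_threshold adjusted-probability threshold.
#' @param preselect set `FALSE` to disable preselection.
#' @return a `wt_cell_selection` data.frame with columns `p_bmd`,
#'   `p_bmd_adj`, `selected`.
#' @export
select_wt_cells <- function(pvals, fdr_threshold = 0.05, preselect = TRUE) {
  ok <- !is.na(pvals)
  adj <- rep(NA_real_, length(pvals))
  adj[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  if (preselect) {
    sel <- !is.na(adj) & adj > fdr_threshold
    if (sum(sel) < 2L) {
      warning("fewer than 2 cells selected as WT reference; keeping all cells")
      sel <- !is.na(pvals)
    }
  } else {
    sel <- !is.na(pvals)
  }
  structure(data.frame(p_bmd = pvals, p_bmd_adj = adj, selected = sel),
            class = c("wt_cell_selection", "data.frame"),
            fdr_threshold = fdr_threshold, preselect = preselect)
}
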