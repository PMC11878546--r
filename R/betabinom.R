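#' Beta-binomial probability mass function
#'
#' Mass of observing `k` WT reads out of `N` when the per-cell WT
#' heteroplasmy is itself Beta(alpha, beta) distributed:
#' `P(X = k) = C(N, k) B(k + alpha, N - k + beta) / B(alpha, beta)`,
#' evaluated through log-beta functions so it stays stable for large `N`
#' and large `alpha + beta`.
#'
#' The mean parameter is `theta = alpha / (alpha + beta)` and the dispersion
#' `phi = 1 / (alpha + beta + 1)`; as `phi -> 0` at fixed `theta` the mass
#' converges to the binomial with probability `theta`.
#'
#' @param k number of WT reads (vectorised).
#' @param N depth.
#' @param alpha,beta strictly positive shape parameters.
#' @return probability vector.
#' @export
bbd_pmf <- function(k, N, alpha, beta) {
  if (!all(is.finite(alpha)) || !all(is.finite(beta)) || any(alpha <= 0) || any(beta <= 0)) {
    stop("alpha and beta must be finite and > 0")
  }
  if (any(k < 0 | k > N | k != round(k))) stop("need integer 0 <= k <= N")
  exp(lchoose(N, k) + lbeta(k + alpha, N - k + beta) - lbeta(alpha, beta))
}

#' Beta-binomial lower tail
#'
#' Inclusive lower-tail probability `P(X <= m | N, alpha, beta)`, the
#' building block of the per-cell mutation test: a cell whose WT read count
#' sits deep in the lower tail of the locus' null has lost WT alleles, i.e.
#' carries a mutation.
#'
#' @param m observed WT read count(s).
#' @param N depth(s), recycled with `m`; `N = 0` yields `NA`.
#' @param fit a `betabinom_fit`, or `NULL` when `alpha`/`beta` are given.
#' @param alpha,beta shape parameters (ignored when `fit` is supplied).
#' @return probability vector with `NA` at zero depth.
#' @export
bbd_lower_tail <- function(m, N, fit = NULL, alpha = fit$alpha, beta = fit$beta) {
  if (!is.null(fit)) stopifnot(inherits(fit, "betabinom_fit"))
  n <- max(length(m), length(N))
  m <- rep_len(m, n); N <- rep_len(N, n)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(m[i]) || is.na(N[i]) || N[i] == 0) next
    out[i] <- min(1, sum(bbd_pmf(0:m[i], N[i], alpha, beta)))
  }
  out
}

#' Fit the beta-binomial null by maximum likelihood
#'
#' Maximises the beta-binomial log-likelihood of the WT read counts of the
#' reference cells over `(log alpha, log beta)` (L-BFGS-B with analytic
#' gradient), starting from a method-of-moments estimate. The precision
#' `s = alpha + beta` is capped at `max_precision`; data with no detectable
#' overdispersion (e.g. drawn from a pure binomial) push the fit to that
#' cap, where the model coincides with the binomial to numerical accuracy.
#'
#' @param m WT allele counts of the reference (preselected WT) cells.
#' @param N depths; cells with `N = 0` are dropped.
#' @param init `"moments"` (default) or `"given"` with `init_par = c(alpha, beta)`.
#' @param init_par optional starting values when `init = "given"`.
#' @param max_precision upper cap on `alpha + beta`.
#' @return a `betabinom_fit`: list with `alpha`, `beta`, `theta`, `phi`,
#'   `precision`, `loglik`, `loglik_init`, `convergence` (0 = optimiser
#'   success), `capped`, `n_cells`.
#' @export
fit_betabinom <- function(m, N, init = c("moments", "given"), init_par = NULL,
                          max_precision = 1e8) {
  init <- match.arg(init)
  stopifnot(length(m) == length(N))
  keep <- which(N > 0)
  m <- as.numeric(m[keep]); N <- as.numeric(N[keep])
  if (length(m) < 2L) stop("need at least 2 cells with positive depth")
  if (any(m < 0) || any(m > N)) stop("counts must satisfy 0 <= m <= N")

  # boundary data carrying no mutant (or no WT) reads at all: the MLE of
  # theta sits on the boundary of (0,1), where every lower-tail probability
  # collapses and dispersion is unidentifiable. Return the binomial limit at
  # the precision cap with a continuity-corrected mean, so one stray read in
  # a deep cell is not infinitely surprising.
  if (sum(N - m) == 0 || sum(m) == 0) {
    t_hat <- (sum(m) + 0.5) / (sum(N) + 1)
    a <- t_hat * max_precision; b <- (1 - t_hat) * max_precision
    ll <- sum(lchoose(N, m) + lbeta(m + a, N - m + b) - lbeta(a, b))
    return(structure(list(alpha = a, beta = b, theta = t_hat,
                          phi = 1 / (max_precision + 1),
                          precision = max_precision,
                          loglik = ll, loglik_init = ll,
                          convergence = 0L, capped = TRUE,
                          n_cells = length(m)),
                     class = "betabinom_fit"))
  }

  # optimise over (logit theta, log s): these axes decouple the sharply
  # identified mean from the weakly identified precision, where a ridge in
  # (log alpha, log beta) would stall quasi-Newton steps
  nll <- function(par) {
    t <- stats::plogis(par[1]); s <- exp(par[2])
    a <- t * s; b <- (1 - t) * s
    -sum(lchoose(N, m) + lbeta(m + a, N - m + b) - lbeta(a, b))
  }
  gr <- function(par) {
    t <- stats::plogis(par[1]); s <- exp(par[2])
    a <- t * s; b <- (1 - t) * s
    da <- sum(digamma(m + a) - digamma(N + s) - digamma(a) + digamma(s))
    db <- sum(digamma(N - m + b) - digamma(N + s) - digamma(b) + digamma(s))
    -c((da - db) * s * t * (1 - t), (t * da + (1 - t) * db) * s)
  }

  if (init == "given") {
    if (is.null(init_par) || any(init_par <= 0)) stop("init_par must be two positive numbers")
    a0 <- init_par[1]; b0 <- init_par[2]
  } else {
    af <- m / N
    t0 <- min(max(mean(af), 1e-6), 1 - 1e-6)
    v <- stats::var(af)
    vb <- t0 * (1 - t0) * mean(1 / N)      # pure-binomial variance of wAF
    denom <- t0 * (1 - t0) - vb
    rho <- if (is.finite(v) && denom > 0) (v - vb) / denom else 0
    rho <- min(max(rho, 1e-6), 1 - 1e-6)   # rho = 1 / (s + 1)
    s0 <- min(max(1 / rho - 1, 1e-2), max_precision)
    a0 <- t0 * s0; b0 <- (1 - t0) * s0
  }
  t0 <- a0 / (a0 + b0)
  u0 <- stats::qlogis(min(max(t0, 1e-8), 1 - 1e-8))
  par0 <- c(u0, log(min(max(a0 + b0, 1e-6), max_precision)))
  lo <- c(stats::qlogis(1e-10), log(1e-6))
  hi <- c(stats::qlogis(1 - 1e-10), log(max_precision))
  starts <- list(par0)
  if (init == "moments") {
    # a second, moderate-precision start guards against the moment estimate
    # landing on the flat near-binomial plateau where line searches stall
    starts <- c(starts, list(c(u0, log(20))))
  }
  opts <- lapply(starts, function(p0) {
    stats::optim(pmin(pmax(p0, lo), hi), nll, gr, method = "L-BFGS-B",
                 lower = lo, upper = hi,
                 control = list(maxit = 1000L, factr = 1e5))
  })
  opt <- opts[[which.min(vapply(opts, `[[`, 0, "value"))]]
  t_hat <- stats::plogis(opt$par[1]); s_hat <- exp(opt$par[2])
  capped <- s_hat >= max_precision * (1 - 1e-6)
  a <- t_hat * s_hat; b <- (1 - t_hat) * s_hat
  structure(list(alpha = a, beta = b,
                 theta = a / (a + b), phi = 1 / (a + b + 1),
                 precision = a + b,
                 loglik = -opt$value, loglik_init = -nll(par0),
                 convergence = opt$convergence, capped = capped,
                 n_cells = length(m)),
            class = "betabinom_fit")
}

#' Per-locus FDR q-values
#'
#' Benjamini-Hochberg step-up adjustment of the per-cell beta-binomial tail
#' probabilities of one locus; the adjusted value is the mutation q-value.
#' Adjustment is always within a locus, never pooled across loci.
#'
#' @param pvals per-cell `P_BBD` values for a single locus (`NA` allowed).
#' @return q-values, same length and order, `NA` preserved.
#' @export
compute_qvalues <- function(pvals) {
  ok <- !is.na(pvals)
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}
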