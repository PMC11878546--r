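# Shared fixture builders and independent oracles for the test suite.

# A tiny hand-specified tensor: 3 cells x 2 loci, counts chosen so depth,
# medians and WT assignment can be verified by eye.
tiny_tensor <- function() {
  loci <- data.frame(contig = "chrM", pos = c(100L, 200L))
  cells <- c("bc1", "bc2", "bc3")
  counts <- list(
    A = rbind(c(5L, 4L, 6L), c(0L, 0L, 0L)),
    C = rbind(c(0L, 1L, 0L), c(2L, 3L, 2L)),
    G = rbind(c(1L, 0L, 0L), c(8L, 7L, 9L)),
    T = rbind(c(0L, 0L, 0L), c(0L, 0L, 1L))
  )
  allele_count_tensor(counts, loci, cells)
}

# Random valid tensor for property tests (biallelic per locus so it can be
# written in both upstream dialects).
random_tensor <- function(n_cells = 6, n_loci = 4, seed = 1) {
  sim <- simulate_dataset(clone_sim_spec(
    n_cells = n_cells, n_loci = n_loci, baseline_theta = 0.9,
    precision = 10, depth_meanlog = 2, depth_sdlog = 0.5, seed = seed
  ))
  sim$tensor
}

# Planted-clone dataset used by calling and acceptance tests: 20 mutant
# cells among 200, mutant heteroplasmy 0.7, depth around 50.
planted_clone_sim <- function(seed = 42, n_loci = 30, planted_locus = 5L) {
  clones <- c(rep("mut", 20), rep("wt", 180))
  spec <- clone_sim_spec(
    n_cells = 200, n_loci = n_loci, clones = clones,
    planted = data.frame(locus = planted_locus, clone = "mut", het = 0.7),
    depth_meanlog = log(50), depth_sdlog = 0.3, seed = seed
  )
  simulate_dataset(spec)
}

# Brute-force Benjamini-Hochberg step-up: sort, scale by m/rank, cumulative
# minimum from the largest p down. Independent of stats::p.adjust.
bh_oracle <- function(p) {
  ok <- !is.na(p)
  pv <- p[ok]
  n <- length(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * pv[o]))[ro]
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  out
}

# Quadrature oracle for the beta-binomial mass: numerically integrate the
# binomial mass against the beta density over the heteroplasmy.
bbd_pmf_quadrature <- function(k, N, alpha, beta) {
  stats::integrate(function(p) stats::dbinom(k, N, p) * stats::dbeta(p, alpha, beta),
                   0, 1, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# Direct maximum-likelihood fit of the two-component binomial mixture by
# Nelder-Mead on the full 3-parameter likelihood; independent of the EM path.
mixture_mle_oracle <- function(m, N) {
  nll <- function(par) {
    w <- stats::plogis(par[1]); p1 <- stats::plogis(par[2]); p2 <- stats::plogis(par[3])
    -sum(log(w * stats::dbinom(m, N, p1) + (1 - w) * stats::dbinom(m, N, p2)))
  }
  o <- stats::optim(c(0, stats::qlogis(0.99), stats::qlogis(0.9999)), nll,
                    method = "Nelder-Mead", control = list(maxit = 5000))
  w <- stats::plogis(o$par[1]); p1 <- stats::plogis(o$par[2]); p2 <- stats::plogis(o$par[3])
  if (p1 >= p2) list(pi_w = p1, pi_m = p2, theta_m = 1 - w)
  else          list(pi_w = p2, pi_m = p1, theta_m = w)
}
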