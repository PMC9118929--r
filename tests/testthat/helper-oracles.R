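# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain-R reimplementations, adaptive integration,
# and brute-force searches at tiny problem sizes.

# exact error function via the normal CDF
erf_exact <- function(z) 2 * pnorm(z * sqrt(2)) - 1

# bivariate normal CDF by 1-D reduction through adaptive quadrature
phi2_oracle <- function(h, k, rho) {
  if (abs(rho) == 1) {
    if (rho == 1) return(pnorm(min(h, k)))
    return(max(pnorm(h) + pnorm(k) - 1, 0))
  }
  integrate(function(x) dnorm(x) * pnorm((k - rho * x) / sqrt(1 - rho^2)),
            -Inf, h, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# brute-force GLB on a 3x3 covariance matrix: coarse-to-fine grid search for
# the maximal removable diagonal keeping the remainder PSD
glb_brute_3x3 <- function(s, refinements = 8) {
  lo <- rep(0, 3)
  hi <- diag(s)
  feasible <- function(e) {
    min(eigen(s - diag(e), symmetric = TRUE, only.values = TRUE)$values) >= -1e-12
  }
  best <- rep(0, 3)
  for (it in seq_len(refinements)) {
    gr <- as.matrix(expand.grid(seq(lo[1], hi[1], length.out = 21),
                                seq(lo[2], hi[2], length.out = 21),
                                seq(lo[3], hi[3], length.out = 21)))
    ok <- apply(gr, 1, feasible)
    cand <- gr[ok, , drop = FALSE]
    best <- cand[which.max(rowSums(cand)), ]
    span <- (hi - lo) / 21 * 4
    lo <- pmax(best - span, 0)
    hi <- pmin(best + span, diag(s))
  }
  1 - sum(best) / sum(s)
}

# tetrachoric by direct grid search of the 4-cell likelihood, with the
# bivariate CDF from the adaptive-integration oracle
tetrachoric_brute <- function(tab, step = 1e-4) {
  n <- sum(tab)
  t1 <- qnorm(sum(tab[1, ]) / n)
  t2 <- qnorm(sum(tab[, 1]) / n)
  rhos <- seq(-0.99, 0.99, by = step)
  ll <- vapply(rhos, function(rho) {
    p00 <- phi2_oracle(t1, t2, rho)
    # column-major cell order of `tab`: (0,0), (1,0), (0,1), (1,1)
    p <- c(p00, pnorm(t2) - p00, pnorm(t1) - p00, 1 - pnorm(t1) - pnorm(t2) + p00)
    sum(as.vector(tab) * log(pmax(p, 1e-12)))
  }, numeric(1))
  rhos[which.max(ll)]
}

# a covariance/correlation matrix with exact one-factor structure
onefactor_matrix <- function(lam, psi2 = 1 - lam^2) {
  s <- tcrossprod(lam) + diag(psi2, length(lam))
  s
}

# simulated binary dataset from freshly sampled parameters
sim_dataset <- function(n, i, seed) {
  set.seed(seed)
  bank <- sample_item_parameters(i)
  list(bank = bank, y = simulate_responses(rnorm(n), bank))
}

quiet_notes <- function(expr) {
  withCallingHandlers(expr,
    dichrel_note = function(w) invokeRestart("muffleWarning"))
}
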