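# Internal raw-vector fast paths for the Monte Carlo harnesses. These mirror
# icc()/simulate_responses()/reliability_*() exactly but skip input
# validation and tibble construction; agreement with the public functions is
# asserted in the test suite.

icc_fast <- function(theta, a, b, D) {
  plogis(D * (outer(theta, b, "-") * rep(a, each = length(theta))))
}

sim_fast <- function(theta, a, b, D) {
  p <- icc_fast(theta, a, b, D)
  (runif(length(p)) < p) * 1L
}

# sum score straight off the probability draw
sumscore_fast <- function(theta, a, b, D) {
  rowSums(sim_fast(theta, a, b, D))
}

rel_quad_fast <- function(a, b, D, x, w) {
  p <- icc_fast(x, a, b, D)
  var_e <- sum(colSums(p * (1 - p) * w))
  tq <- rowSums(p)
  var_t <- max(sum(tq^2 * w) - sum(tq * w)^2, 0)
  var_t / (var_t + var_e)
}

# analytic route; negative per-item true-score variances clipped silently
# (the public reliability_analytic() flags them)
rel_analytic_fast <- function(a, b) {
  z <- a * b / sqrt(2 * (1 + a^2))
  m <- c(0.278393, 0.230389, 0.000972, 0.078108)
  az <- abs(z)
  erf <- sign(z) * (1 - (1 + m[1] * az + m[2] * az^2 + m[3] * az^3 + m[4] * az^4)^-4)
  pi_i <- (1 - erf) / 2
  m_i <- 0.2646 - 0.118 * a + 0.0187 * a^2
  d_i <- 0.7427 + 0.7081 / a + 0.0074 / a^2
  var_e <- m_i * exp(-0.5 * (b / d_i)^2)
  var_t <- sum(sqrt(pmax(pi_i * (1 - pi_i) - var_e, 0)))^2
  var_t / (var_t + sum(var_e))
}
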