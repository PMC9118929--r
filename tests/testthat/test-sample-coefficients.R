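test_that("sample covariance is unbiased, symmetric, and flags constants", {
  y <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0), c(0, 0, 0))
  s <- covariance_matrix(y)
  expect_equal(s, t(s))
  expect_equal(diag(s), c(0.25, 1 / 3, 0.25), ignore_attr = TRUE)
  ydup <- cbind(y[, 2], y[, 2])
  sdup <- covariance_matrix(ydup)
  expect_equal(sdup[1, 2], sdup[1, 1])
  expect_warning(covariance_matrix(cbind(y, 1)), class = "dichrel_degenerate")
  # independent items: off-diagonals vanish within sampling error
  set.seed(301)
  yi <- matrix(rbinom(2e5 * 3, 1, 0.5), ncol = 3)
  si <- covariance_matrix(yi)
  expect_true(all(abs(si[upper.tri(si)]) < 3 * 0.25 / sqrt(2e5)))
})

test_that("alpha reproduces the hand-computed toy value and its extremes", {
  y <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0), c(0, 0, 0))
  # item variances 1/4, 1/3, 1/4; Var(Y) = 5/3
  expect_equal(cronbach_alpha(y), 0.75)
  same <- cbind(y[, 2], y[, 2], y[, 2])
  expect_equal(cronbach_alpha(same), 1)
  # exactly uncorrelated items via a diagonal covariance matrix
  expect_equal(cronbach_alpha(diag(c(0.2, 0.25, 0.21))), 0)
  expect_error(cronbach_alpha(matrix(0, 3, 3)), "zero variance")
})

test_that("alpha on parallel items follows the Spearman-Brown formula", {
  v <- 0.25; cv <- 0.1
  rho1 <- cv / v
  for (k in c(2, 5, 9)) {
    s <- matrix(cv, k, k); diag(s) <- v
    sb <- k * rho1 / (1 + (k - 1) * rho1)
    expect_equal(cronbach_alpha(s), sb, tolerance = 1e-12)
  }
})

test_that("GLB solves its defining trace-maximization program", {
  # independent items: all variance is removable, GLB = 0
  expect_lt(glb(diag(c(1, 2, 3))), 1e-6)
  # rank-1 matrix: nothing is removable, GLB = 1
  sig <- c(0.8, 0.6, 0.7)
  expect_equal(glb(tcrossprod(sig)), 1)
  # brute-force oracle on small one-factor-plus-noise instances
  set.seed(302)
  for (k in 1:3) {
    lam <- runif(3, 0.3, 0.8)
    s <- onefactor_matrix(lam, runif(3, 0.2, 0.6))
    expect_equal(glb(s), glb_brute_3x3(s), tolerance = 1e-4)
  }
  expect_error(glb(matrix(c(1, 2, 2, 1), 2)), "positive semidefinite")
})

test_that("GLB handles singular matrices by null-space deflation", {
  # rank-1 block (nothing removable) + independent noise block (all removable)
  s <- matrix(0, 4, 4)
  s[1:2, 1:2] <- tcrossprod(c(1, 0.8))
  s[3, 3] <- 1; s[4, 4] <- 1
  expect_equal(glb(s), 1 - 2 / sum(s), tolerance = 1e-6)
})

test_that("alpha never exceeds the GLB across simulated datasets", {
  set.seed(303)
  for (k in 1:60) {
    d <- sim_dataset(n = 60, i = sample(4:9, 1), seed = 303 + k)
    s <- quiet_notes(covariance_matrix(d$y))
    expect_lte(cronbach_alpha(s), glb(s) + 1e-7)
  }
})

test_that("GLB is monotone in common covariance and bounded in [0, 1]", {
  lam <- rep(0.5, 4)
  glbs <- vapply(c(0.05, 0.1, 0.15, 0.2), function(c0) {
    s <- matrix(c0, 4, 4); diag(s) <- 0.25
    glb(s)
  }, numeric(1))
  expect_true(all(diff(glbs) > -1e-9))
  expect_true(all(glbs >= 0 & glbs <= 1))
})

test_that("minres recovers an exact one-factor structure", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  r <- onefactor_matrix(lam)
  sol <- factor_minres(r)
  expect_lt(max(abs(sol$loading - lam)), 1e-6)
  expect_lt(max(abs(sol$uniqueness - (1 - lam^2))), 1e-5)
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  sol_p <- factor_minres(r[perm, perm])
  expect_lt(max(abs(sol_p$loading - lam[perm])), 1e-6)
  # an identity matrix has no common factor (flagged degenerate)
  expect_warning(sol0 <- factor_minres(diag(4)), class = "dichrel_degenerate")
  expect_lt(max(abs(sol0$loading)), 1e-4)
})

test_that("omega follows its closed form and boundary cases", {
  expect_equal(omega_total(rep(0, 4), rep(1, 4)), 0)
  expect_equal(omega_total(rep(1, 4), rep(0, 4)), 1)
  expect_equal(omega_total(rep(0.6, 4), rep(0.64, 4)), 2.4^2 / (5.76 + 2.56))
  expect_error(omega_total(rep(0, 3), rep(0, 3)), "Degenerate")
})

test_that("omega equals alpha under tau-equivalence", {
  r <- onefactor_matrix(rep(0.55, 6))
  expect_equal(omega_total(factor_minres(r)), cronbach_alpha(r), tolerance = 1e-6)
})

test_that("ML CFA recovers an exact structure with zero discrepancy", {
  lam <- c(0.5, 0.45, 0.4, 0.3)
  psi2 <- c(0.2, 0.22, 0.25, 0.3)
  s <- onefactor_matrix(lam, psi2)
  sol <- cfa_ml_onefactor(s, n = 500)
  expect_lt(max(abs(sol$loading - lam)), 1e-5)
  expect_lt(max(abs(sol$uniqueness - psi2)), 1e-5)
  expect_lt(attr(sol, "discrepancy"), 1e-9)
  # loadings are reported with nonnegative sum despite sign indeterminacy
  expect_gte(sum(sol$loading), 0)
})

test_that("minres and CFA omegas agree on large continuous one-factor data", {
  set.seed(304)
  n <- 5e4
  lam <- c(0.7, 0.6, 0.55, 0.5, 0.45)
  theta <- rnorm(n)
  yc <- outer(theta, lam) + matrix(rnorm(n * 5), n) %*% diag(sqrt(1 - lam^2))
  om_minres <- omega_total(factor_minres(cor(yc)))
  om_cfa <- omega_total(cfa_ml_onefactor(stats::cov(yc), n))
  expect_lt(abs(om_minres - om_cfa), 0.01)
})
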