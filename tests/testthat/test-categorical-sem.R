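test_that("thresholds are normal quantiles of the zero proportion", {
  y <- cbind(rep(c(0L, 1L), each = 50))
  expect_equal(thresholds(y)[[1]], 0)
  y2 <- cbind(c(rep(0L, 8413), rep(1L, 1587)))
  expect_equal(thresholds(y2)[[1]], qnorm(0.8413), tolerance = 1e-12)
  expect_equal(qnorm(0.8413), 1, tolerance = 1e-3)
  # symmetry: swapping 0s and 1s negates the threshold
  y3 <- cbind(c(rep(0L, 30), rep(1L, 70)))
  expect_equal(thresholds(y3)[[1]], -thresholds(1L - y3)[[1]])
  expect_error(thresholds(cbind(rep(1L, 10))), "no variation")
})

test_that("bivariate normal CDF matches closed forms and adaptive integration", {
  expect_equal(bivariate_normal_cdf(0, 0, 0), 0.25)
  expect_equal(bivariate_normal_cdf(0, 0, 0.5), 0.25 + asin(0.5) / (2 * pi),
               tolerance = 1e-12)
  tau <- 0.7
  expect_equal(bivariate_normal_cdf(tau, tau, 1), pnorm(tau))
  expect_equal(bivariate_normal_cdf(1.2, -0.4, 1), pnorm(-0.4))
  cases <- expand.grid(h = c(-2, -0.5, 0.3, 1.5),
                       k = c(-1.1, 0, 0.8),
                       rho = c(-0.95, -0.5, 0, 0.6, 0.95, 0.999))
  for (m in seq_len(nrow(cases))) {
    expect_equal(bivariate_normal_cdf(cases$h[m], cases$k[m], cases$rho[m]),
                 phi2_oracle(cases$h[m], cases$k[m], cases$rho[m]),
                 tolerance = 1e-8)
  }
})

test_that("tetrachoric correlation solves the two-step likelihood", {
  # independence: counts proportional to the margins
  tab0 <- outer(c(60, 40), c(30, 70)) / 100
  expect_lt(abs(tetrachoric(tab0)), 1e-6)
  # brute-force likelihood grid as oracle
  tab <- matrix(c(40, 10, 10, 40), 2)
  expect_equal(tetrachoric(tab), tetrachoric_brute(tab), tolerance = 1e-4)
  tab2 <- matrix(c(55, 25, 10, 30), 2)
  expect_equal(tetrachoric(tab2), tetrachoric_brute(tab2), tolerance = 1e-4)
  expect_error(tetrachoric(matrix(c(5, 5, 0, 0), 2)), "margin")
  expect_warning(tetrachoric(matrix(c(50, 10, 0, 40), 2)),
                 class = "dichrel_continuity")
})

test_that("tetrachoric recovers the generating latent correlation", {
  set.seed(401)
  z <- MASS::mvrnorm(1e6, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2))
  y1 <- (z[, 1] > 0.3) * 1L
  y2 <- (z[, 2] > -0.2) * 1L
  tab <- matrix(as.numeric(table(factor(y1, 0:1), factor(y2, 0:1))), 2)
  expect_lt(abs(tetrachoric(tab) - 0.5), 0.01)
})

test_that("the vectorized tetrachoric matrix agrees with per-pair estimates", {
  d <- sim_dataset(n = 800, i = 5, seed = 402)
  r <- tetrachoric_matrix(d$y)
  expect_equal(r, t(r))
  expect_equal(diag(r), rep(1, 5), ignore_attr = TRUE)
  for (pair in list(c(1, 2), c(2, 5), c(3, 4))) {
    tab <- table(factor(d$y[, pair[1]], 0:1), factor(d$y[, pair[2]], 0:1))
    expect_equal(r[pair[1], pair[2]], tetrachoric(matrix(as.numeric(tab), 2)),
                 tolerance = 1e-5)
  }
})

test_that("probit loadings recover exact structure and flag degeneracy", {
  lam <- c(0.7, 0.6, 0.5, 0.4)
  r <- onefactor_matrix(lam)
  sol <- probit_loadings(r)
  expect_lt(max(abs(sol$loading - lam)), 1e-6)
  expect_warning(sol0 <- probit_loadings(diag(4)), class = "dichrel_degenerate")
  expect_lt(max(abs(sol0$loading)), 1e-4)
})

test_that("Green-Yang reliability collapses to zero without common variance", {
  gy <- green_yang_reliability(tau = c(-0.5, 0, 0.5), loadings = rep(0, 3))
  expect_equal(gy$reliability, 0)
  expect_error(green_yang_reliability(0, 1.2), "Inadmissible")
})

test_that("population Green-Yang equals probit-link quadrature reliability", {
  set.seed(403)
  for (k in 1:5) {
    bank <- sample_item_parameters(sample(c(8, 15, 30), 1))
    lam <- bank$a / sqrt(1 + bank$a^2)
    tau <- lam * bank$b
    gy <- green_yang_reliability(tau, lam)$reliability
    dq <- reliability_quadrature(bank, trait_grid(401, -8, 8),
                                 link = "probit")$reliability
    expect_lt(abs(gy - dq), 1e-3)
  }
})

test_that("the categorical pipeline converges to its population value", {
  set.seed(404)
  bank <- sample_item_parameters(8)
  lam <- bank$a / sqrt(1 + bank$a^2)
  tau <- lam * bank$b
  gy_pop <- green_yang_reliability(tau, lam)$reliability
  y <- simulate_responses(rnorm(5e4), bank, link = "probit")
  gy_est <- reliability_green_yang(y)$reliability
  expect_lt(abs(gy_est - gy_pop), 0.01)
})

test_that("Green-Yang is invariant to reversing the item coding", {
  d <- sim_dataset(n = 2000, i = 6, seed = 405)
  g1 <- reliability_green_yang(d$y)$reliability
  g2 <- reliability_green_yang(1L - d$y)$reliability
  expect_equal(g1, g2, tolerance = 1e-10)
})

test_that("model-implied true variance never exceeds total variance", {
  set.seed(406)
  for (k in 1:10) {
    lam <- runif(5, 0.1, 0.9)
    tau <- rnorm(5, 0, 0.8)
    gy <- green_yang_reliability(tau, lam)
    expect_lte(gy$var_t, gy$var_y + 1e-12)
    expect_gte(gy$reliability, 0)
    expect_lte(gy$reliability, 1)
  }
})
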