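test_that("the polynomial error function is odd, zero at zero, and accurate", {
  expect_equal(erf_approx(0), 0)
  z <- seq(-4, 4, by = 0.37)
  expect_equal(erf_approx(-z), -erf_approx(z))
  zz <- seq(0, 6, by = 0.001)
  expect_lt(max(abs(erf_approx(zz) - erf_exact(zz))), 5e-4)
})

test_that("analytic marginal probabilities behave and track quadrature", {
  q0 <- analytic_item_quantities(item_bank(a = 0.8, b = 0))
  expect_equal(q0$pi, 0.5)
  qa <- analytic_item_quantities(item_bank(a = c(0.6, 0.6), b = c(1.3, -1.3)))
  expect_equal(sum(qa$pi), 1)  # odd symmetry in b
  # logistic/probit gap bounds the discrepancy against direct integration
  b1 <- item_bank(a = 0.5, b = 1)
  pi_q <- quadrature_item_quantities(b1, trait_grid(1001, -8, 8))$pi
  expect_lt(abs(analytic_item_quantities(b1)$pi - pi_q), 0.01)
})

test_that("analytic item error variance matches its printed constants and decays", {
  q <- analytic_item_quantities(item_bank(a = 1, b = 0))
  expect_equal(q$m, 0.2646 - 0.118 + 0.0187)
  expect_equal(q$var_e, 0.1653, tolerance = 1e-12)
  far <- analytic_item_quantities(item_bank(a = 1, b = 25))
  expect_lt(far$var_e, 1e-10)
  # agreement with the quadrature error variance across the sampled range
  set.seed(201)
  bank <- item_bank(a = runif(40, 0.2, 1.5), b = runif(40, -2, 2))
  ve_q <- quadrature_item_quantities(bank, trait_grid(1001, -8, 8))$var_e
  ve_a <- analytic_item_quantities(bank)$var_e
  expect_lt(max(abs(ve_a - ve_q)), 0.02)
})

test_that("quadrature error variance matches adaptive integration", {
  g <- trait_grid()
  flat <- quadrature_item_quantities(item_bank(a = 1e-10, b = 0), g)
  expect_equal(flat$var_e, 0.25, tolerance = 1e-10)
  for (pars in list(c(0.2, -2), c(0.7, 0), c(1.5, 2))) {
    bank <- item_bank(a = pars[1], b = pars[2])
    direct <- integrate(function(th) {
      p <- plogis(1.702 * pars[1] * (th - pars[2]))
      p * (1 - p) * dnorm(th)
    }, -Inf, Inf, rel.tol = 1e-12)$value
    q <- quadrature_item_quantities(bank, g)
    expect_equal(q$var_e, direct, tolerance = 1e-6)
    # conditional variance can never exceed the marginal Bernoulli variance
    expect_lte(q$var_e, q$pi * (1 - q$pi))
  }
})

test_that("quadrature variance decomposition is exact per item", {
  set.seed(202)
  g <- trait_grid()
  bank <- sample_item_parameters(25)
  q <- quadrature_item_quantities(bank, g)
  for (j in seq_len(nrow(bank))) {
    one <- reliability_quadrature(bank[j, ], g)
    expect_equal(one$var_t + one$var_e, q$pi[j] * (1 - q$pi[j]), tolerance = 1e-10)
  }
})

test_that("true-score variance limits: flat items, duplication scaling", {
  g <- trait_grid()
  flat <- reliability_quadrature(item_bank(a = rep(1e-10, 5), b = rep(0, 5)), g)
  expect_lt(flat$var_t, 1e-12)
  bank <- item_bank(a = c(0.5, 1.1), b = c(-0.4, 0.8))
  dup <- item_bank(a = rep(bank$a, 2), b = rep(bank$b, 2))
  r1 <- reliability_quadrature(bank, g)
  r2 <- reliability_quadrature(dup, g)
  expect_equal(r2$var_t, 4 * r1$var_t, tolerance = 1e-10)
  expect_equal(r2$var_e, 2 * r1$var_e, tolerance = 1e-10)
})

test_that("analytic true-score variance composes the single-item terms", {
  bank1 <- item_bank(a = 0.9, b = 0.3)
  q <- analytic_item_quantities(bank1)
  r1 <- reliability_analytic(bank1)
  expect_equal(r1$var_t, q$pi * (1 - q$pi) - q$var_e)
  twin <- item_bank(a = rep(0.9, 2), b = rep(0.3, 2))
  expect_equal(reliability_analytic(twin)$var_t, 4 * r1$var_t, tolerance = 1e-12)
})

test_that("reliability ratio handles boundary variance splits", {
  expect_equal(reliability_from_variances(3, 1), 0.75)
  expect_equal(reliability_from_variances(5, 0), 1)
  expect_equal(reliability_from_variances(0, 2), 0)
  expect_error(reliability_from_variances(0, 0), "zero")
  expect_error(reliability_from_variances(-1, 2), "nonnegative")
})

test_that("reliability extremes: strong long tests and noise-only items", {
  strong <- item_bank(a = rep(2, 150), b = rep(0, 150))
  expect_gt(reliability_quadrature(strong)$reliability, 0.99)
  noise <- item_bank(a = 1e-9, b = 0)
  expect_lt(reliability_quadrature(noise)$reliability, 1e-6)
})

test_that("analytic reliability exceeds quadrature reliability on average", {
  set.seed(203)
  diffs <- replicate(500, {
    bank <- sample_item_parameters(sample(10:70, 1))
    quiet_notes(reliability_analytic(bank)$reliability) -
      reliability_quadrature(bank)$reliability
  })
  expect_gt(mean(diffs), 0)
})

test_that("quadrature reliability grows when an informative item is appended", {
  set.seed(204)
  g <- trait_grid()
  for (k in 1:20) {
    bank <- sample_item_parameters(sample(5:30, 1))
    extra <- sample_item_parameters(1)
    grown <- item_bank(c(bank$a, extra$a), c(bank$b, extra$b))
    expect_gt(reliability_quadrature(grown, g)$reliability,
              reliability_quadrature(bank, g)$reliability)
  }
})

test_that("the default grid is dense enough for six-figure reliability", {
  set.seed(205)
  for (k in 1:10) {
    bank <- sample_item_parameters(sample(10:70, 1))
    r101 <- reliability_quadrature(bank, trait_grid(101))$reliability
    r2001 <- reliability_quadrature(bank, trait_grid(2001))$reliability
    expect_lt(abs(r101 - r2001), 1e-6)
  }
})

test_that("reliability objects tidy and glance cleanly", {
  r <- reliability_quadrature(item_bank(a = c(0.5, 1), b = c(0, 1)))
  g <- glance(r)
  expect_equal(g$reliability, r$reliability)
  expect_equal(nrow(tidy(r)), 2)
  expect_output(print(r), "quadrature")
})
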