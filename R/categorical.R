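# Nonlinear (categorical) SEM reliability for dichotomous items: thresholds
# on an underlying standard-normal variable, tetrachoric correlations by
# two-step ML, probit-metric one-factor loadings, and the reliability of the
# sum score implied by that model (Green-Yang coefficient). The bivariate
# normal CDF used throughout is evaluated by Gauss-Legendre quadrature of
# the single-integral (Drezner-style) representation.

.dichrel_env <- new.env(parent = emptyenv())

gl_nodes <- function(n = 96) {
  key <- paste0("gl", n)
  if (is.null(.dichrel_env[[key]])) {
    .dichrel_env[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  .dichrel_env[[key]]
}

#' Standard bivariate normal CDF
#'
#' `P(Z1 <= h, Z2 <= k)` under a standard bivariate normal with correlation
#' `rho`, via the identity
#' `Phi2(h, k, rho) = Phi(h) Phi(k) + (1 / 2 pi) int_0^asin(rho)
#' exp(-(h^2 + k^2 - 2 h k sin t) / (2 cos^2 t)) dt`,
#' integrated with fixed Gauss-Legendre nodes. All three arguments are
#' vectorized (recycled to a common length).
#'
#' @param h,k Upper limits.
#' @param rho Correlation(s) in `[-1, 1]`.
#' @return Probabilities, same length as the recycled inputs.
#' @examples
#' bivariate_normal_cdf(0, 0, 0.5)
#' @export
bivariate_normal_cdf <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(h, n); k <- rep_len(k, n); rho <- rep_len(rho, n)
  if (any(abs(rho) > 1)) abort("`rho` must lie in [-1, 1].")
  gl <- gl_nodes()
  up <- asin(rho)
  # theta_{n x q} = t_q * asin(rho_n)
  theta <- outer(up, gl$x)
  s <- sin(theta); cs2 <- pmax(cos(theta)^2, .Machine$double.eps)
  integrand <- exp(-((h^2 + k^2) - 2 * h * k * s) / (2 * cs2))
  out <- pnorm(h) * pnorm(k) + (up / (2 * pi)) * as.vector(integrand %*% gl$w)
  # exact limits guard against quadrature residue at |rho| = 1
  at1 <- abs(rho) == 1
  if (any(at1)) {
    out[at1 & rho == 1] <- pnorm(pmin(h, k))[at1 & rho == 1]
    out[at1 & rho == -1] <- pmax(pnorm(h) + pnorm(k) - 1, 0)[at1 & rho == -1]
  }
  pmin(pmax(out, 0), 1)
}

# standard bivariate normal density at (h, k); derivative of Phi2 in rho
bivariate_normal_pdf <- function(h, k, rho) {
  om <- 1 - rho^2
  exp(-(h^2 - 2 * rho * h * k + k^2) / (2 * om)) / (2 * pi * sqrt(om))
}

#' Item thresholds under the underlying-variable model
#'
#' The threshold is the standard-normal quantile of the proportion of 0
#' responses, `tau_i = qnorm(P(Y_i = 0))`, so that `P(Y_i = 1) =
#' 1 - Phi(tau_i)`. Items with no variation have no finite threshold and
#' raise an error.
#'
#' @param responses Binary response matrix or data frame.
#' @return Named numeric vector of thresholds, one per item.
#' @export
thresholds <- function(responses) {
  responses <- as_response_matrix(responses)
  p0 <- colMeans(responses == 0)
  bad <- which(p0 == 0 | p0 == 1)
  if (length(bad) > 0) {
    abort(sprintf("Item %d has no variation (all %s); threshold undefined.",
                  bad[1], if (p0[bad[1]] == 1) "0s" else "1s"))
  }
  stats::setNames(qnorm(p0), colnames(responses))
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Two-step maximum likelihood: thresholds are fixed at the normal quantiles
#' of the margins, then the latent correlation maximizes the four-cell
#' multinomial likelihood under a standard bivariate normal. The estimate is
#' confined to `[-0.999, 0.999]`. Tables with an empty cell get a continuity
#' correction (+0.5 to every cell, flagged) unless `strict = TRUE`.
#'
#' @param tab 2x2 table of counts; rows index the first item's 0/1, columns
#'   the second's.
#' @param strict Error on empty cells instead of applying the correction.
#' @return The tetrachoric correlation estimate.
#' @examples
#' tetrachoric(matrix(c(40, 10, 10, 40), 2))
#' @export
tetrachoric <- function(tab, strict = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0)) abort("`tab` must be a 2x2 count table.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("A margin of the 2x2 table is zero; tetrachoric undefined.")
  }
  if (any(tab == 0)) {
    if (strict) abort("Empty cell in 2x2 table (strict mode).")
    dichrel_note("Empty cell in 2x2 table; +0.5 continuity correction applied.",
                 class = "dichrel_continuity")
    tab <- tab + 0.5
  }
  n <- sum(tab)
  tau1 <- qnorm(rowSums(tab)[1] / n)
  tau2 <- qnorm(colSums(tab)[1] / n)
  negll <- function(rho) {
    p <- cell_probs(tau1, tau2, rho)
    -sum(tab * log(p))
  }
  opt <- optimize(negll, c(-0.999, 0.999), tol = 1e-7)
  unname(opt$minimum)
}

# cell probabilities in the table's column-major order: (0,0), (1,0), (0,1), (1,1)
cell_probs <- function(tau1, tau2, rho) {
  p00 <- bivariate_normal_cdf(tau1, tau2, rho)
  p <- c(p00,
         pnorm(tau2) - p00,
         pnorm(tau1) - p00,
         1 - pnorm(tau1) - pnorm(tau2) + p00)
  pmax(p, 1e-12)
}

#' Tetrachoric correlation matrix
#'
#' Pairwise two-step ML tetrachorics for all item pairs, computed with a
#' vectorized safeguarded Newton/bisection search on the score function
#' (the derivative of each pair's log-likelihood in the latent correlation).
#' Zero cells get the +0.5 continuity correction, flagged once.
#'
#' @param responses Binary response matrix or data frame, I >= 2 items, each
#'   with both response values.
#' @return The I x I tetrachoric correlation matrix (unit diagonal).
#' @export
tetrachoric_matrix <- function(responses) {
  responses <- as_response_matrix(responses)
  tau <- thresholds(responses)
  i <- ncol(responses)
  pair <- which(upper.tri(diag(i)), arr.ind = TRUE)
  n <- nrow(responses)
  # joint counts for all pairs at once
  x <- responses
  n11 <- crossprod(x)[pair]
  ci <- colSums(x)
  n10 <- ci[pair[, 1]] - n11   # item i = 1, item j = 0
  n01 <- ci[pair[, 2]] - n11
  n00 <- n - n11 - n10 - n01
  counts <- cbind(n00 = n00, n01 = n01, n10 = n10, n11 = n11)
  zero <- rowSums(counts == 0) > 0
  if (any(zero)) {
    dichrel_note(sprintf("%d item pair(s) had an empty 2x2 cell; +0.5 continuity correction applied.",
                         sum(zero)),
                 class = "dichrel_continuity")
    counts[zero, ] <- counts[zero, ] + 0.5
  }
  ntot <- rowSums(counts)
  # two-step: thresholds recomputed from (possibly corrected) pair margins
  t1 <- qnorm((counts[, "n00"] + counts[, "n01"]) / ntot)
  t2 <- qnorm((counts[, "n00"] + counts[, "n10"]) / ntot)
  rho <- tetrachoric_solve(counts, t1, t2)
  r <- diag(i)
  r[pair] <- rho
  r[pair[, c(2, 1)]] <- rho
  dimnames(r) <- list(colnames(responses), colnames(responses))
  r
}

# vectorized root-finding for the tetrachoric score equation, one rho per row
tetrachoric_solve <- function(counts, t1, t2, lo = -0.999, hi = 0.999) {
  score <- function(rho) {
    p00 <- bivariate_normal_cdf(t1, t2, rho)
    p01 <- pmax(pnorm(t1) - p00, 1e-12)
    p10 <- pmax(pnorm(t2) - p00, 1e-12)
    p11 <- pmax(1 - pnorm(t1) - pnorm(t2) + p00, 1e-12)
    p00 <- pmax(p00, 1e-12)
    bivariate_normal_pdf(t1, t2, rho) *
      (counts[, "n00"] / p00 - counts[, "n01"] / p01 -
         counts[, "n10"] / p10 + counts[, "n11"] / p11)
  }
  m <- length(t1)
  a <- rep(lo, m); b <- rep(hi, m)
  fa <- score(a); fb <- score(b)
  # score is decreasing through the root; same sign at both ends => boundary
  at_lo <- fa <= 0
  at_hi <- fb >= 0
  for (iter in 1:45) {
    mid <- (a + b) / 2
    fm <- score(mid)
    go_right <- fm > 0
    a[go_right] <- mid[go_right]
    b[!go_right] <- mid[!go_right]
  }
  rho <- (a + b) / 2
  rho[at_lo] <- lo
  rho[at_hi] <- hi
  rho
}

#' Probit-metric one-factor loadings from a tetrachoric matrix
#'
#' Unweighted least squares on the off-diagonal elements of the tetrachoric
#' correlation matrix (the same minres criterion used for linear omega),
#' with loadings kept strictly inside (-1, 1) and the sign fixed so
#' `sum(lambda) >= 0`.
#'
#' @param r_poly Tetrachoric/polychoric correlation matrix, I >= 3.
#' @return A `factor_solution` tibble on the probit metric.
#' @export
probit_loadings <- function(r_poly) {
  factor_minres(r_poly)
}

#' Green-Yang categorical reliability
#'
#' Reliability of the sum score implied by the categorical one-factor model:
#' the model-implied true-score variance of the sum over its model-implied
#' total variance. Each covariance entry has the form
#' `Phi2(tau_i, tau_j; c) - Phi(tau_i) Phi(tau_j)` with `c = lambda_i
#' lambda_j` in the numerator (including `i = j`) and `c` equal to the
#' tetrachoric correlation (1 on the diagonal) in the denominator.
#'
#' @param tau Thresholds, one per item.
#' @param loadings Probit-metric loadings, `|lambda| < 1`.
#' @param r_poly Tetrachoric correlation matrix (unit diagonal); defaults to
#'   the model-implied matrix `lambda lambda'` with unit diagonal, which
#'   gives the population coefficient.
#' @return An object of class `gy_reliability` (list with `reliability`,
#'   `var_t`, `var_y`, `tau`, `loadings`); supports [glance()].
#' @examples
#' lam <- rep(0.6, 4)
#' green_yang_reliability(tau = rep(0, 4), loadings = lam)
#' @export
green_yang_reliability <- function(tau, loadings, r_poly = NULL) {
  i <- length(tau)
  if (length(loadings) != i) abort("`tau` and `loadings` must have equal length.")
  if (any(abs(loadings) >= 1)) abort("Inadmissible solution: |loading| >= 1.")
  if (is.null(r_poly)) {
    r_poly <- tcrossprod(loadings)
    diag(r_poly) <- 1
  }
  if (!all(dim(r_poly) == c(i, i))) abort("`r_poly` has the wrong dimension.")
  ti <- rep(tau, times = i)
  tj <- rep(tau, each = i)
  c_num <- as.vector(tcrossprod(loadings))
  c_den <- as.vector(r_poly)
  phi_prod <- pnorm(ti) * pnorm(tj)
  var_t <- sum(bivariate_normal_cdf(ti, tj, c_num) - phi_prod)
  var_y <- sum(bivariate_normal_cdf(ti, tj, c_den) - phi_prod)
  if (var_y <= 0) abort("Model-implied total variance is nonpositive.")
  structure(
    list(reliability = max(0, var_t / var_y), var_t = var_t, var_y = var_y,
         tau = tau, loadings = loadings),
    class = "gy_reliability"
  )
}

#' @export
print.gy_reliability <- function(x, ...) {
  cat(sprintf("Categorical (Green-Yang) reliability: %.4f  [Var(T) = %.4f, Var(Y) = %.4f]\n",
              x$reliability, x$var_t, x$var_y))
  invisible(x)
}

#' @export
glance.gy_reliability <- function(x, ...) {
  tibble(n_items = length(x$tau), var_t = x$var_t, var_y = x$var_y,
         reliability = x$reliability)
}

#' Green-Yang reliability from raw responses
#'
#' The full categorical pipeline: thresholds, tetrachoric correlation
#' matrix, probit-metric one-factor loadings by unweighted least squares,
#' then the Green-Yang coefficient with the sample tetrachoric matrix in the
#' denominator.
#'
#' @param responses Binary response matrix or data frame, I >= 3.
#' @return A `gy_reliability` object.
#' @examples
#' set.seed(1)
#' y <- simulate_responses(rnorm(400), sample_item_parameters(6))
#' reliability_green_yang(y)
#' @export
reliability_green_yang <- function(responses) {
  responses <- as_response_matrix(responses)
  tau <- thresholds(responses)
  r_poly <- tetrachoric_matrix(responses)
  sol <- probit_loadings(r_poly)
  green_yang_reliability(tau, sol$loading, r_poly)
}
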