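# One-factor linear models behind omega: minres (ordinary least squares on
# the correlation matrix) and normal-theory maximum likelihood CFA on the
# covariance matrix. Both return a common `factor_solution` object.

new_factor_solution <- function(item, loadings, uniqueness, method,
                                converged, iterations, heywood,
                                discrepancy = NA_real_) {
  out <- tibble(item = item, loading = loadings, uniqueness = uniqueness)
  attr(out, "method") <- method
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iterations
  attr(out, "heywood") <- heywood
  attr(out, "discrepancy") <- discrepancy
  class(out) <- c("factor_solution", class(out))
  out
}

#' @export
glance.factor_solution <- function(x, ...) {
  tibble(method = attr(x, "method"),
         n_items = nrow(x),
         omega = omega_total(x),
         converged = attr(x, "converged"),
         iterations = attr(x, "iterations"),
         heywood = attr(x, "heywood"),
         discrepancy = attr(x, "discrepancy"))
}

#' @export
tidy.factor_solution <- function(x, ...) {
  as_tibble(unclass(x)[c("item", "loading", "uniqueness")])
}

# lower bound on uniquenesses; keeps solutions admissible and flags Heywood
# cases instead of silently absorbing them
UNIQUENESS_FLOOR <- 1e-3

#' One-factor minres (ordinary least squares) factor analysis
#'
#' Minimizes the sum of squared off-diagonal residuals of
#' `R - lambda lambda'` over the loading vector, the default extraction used
#' for omega on a Pearson correlation matrix. Uniquenesses are
#' `1 - lambda^2`, floored at `1e-3`; loadings hitting the admissibility
#' bound are flagged as Heywood cases. The loading sign is fixed so
#' `sum(lambda) >= 0`.
#'
#' @param r A correlation matrix (square, symmetric, unit diagonal), I >= 3.
#' @return A `factor_solution` tibble (columns `item`, `loading`,
#'   `uniqueness`) with fit metadata attributes; see [glance()].
#' @examples
#' lam <- c(0.8, 0.7, 0.6, 0.5)
#' r <- tcrossprod(lam); diag(r) <- 1
#' factor_minres(r)
#' @export
factor_minres <- function(r) {
  if (!is_square_symmetric(r)) abort("`r` must be a square symmetric matrix.")
  i <- nrow(r)
  if (i < 3) abort("At least 3 items are required for a one-factor solution.")
  if (max(abs(diag(r) - 1)) > 1e-8) abort("`r` must have a unit diagonal.")
  off <- upper.tri(r)
  objective <- function(lam) {
    res <- r - tcrossprod(lam)
    sum(res[off]^2)
  }
  gradient <- function(lam) {
    res <- r - tcrossprod(lam)
    diag(res) <- 0
    -2 * as.vector(res %*% lam)
  }
  bound <- sqrt(1 - UNIQUENESS_FLOOR)
  lam0 <- minres_start(r, bound)
  fit <- optim(lam0, objective, gradient, method = "L-BFGS-B",
               lower = -bound, upper = bound,
               control = list(maxit = 500, factr = 1e4))
  lam <- fit$par
  if (sum(lam) < 0) lam <- -lam
  heywood <- any(abs(abs(lam) - bound) < 1e-10)
  if (heywood) {
    dichrel_note("minres solution at the admissibility bound (Heywood case).",
                 class = "dichrel_heywood")
  }
  if (fit$convergence != 0) {
    abort(sprintf("minres failed to converge: %s", fit$message %||% fit$convergence))
  }
  if (max(abs(lam)) < 1e-3) {
    dichrel_note("All loadings are essentially zero (no common variance).",
                 class = "dichrel_degenerate")
  }
  items <- colnames(r) %||% sprintf("item%02d", seq_len(i))
  new_factor_solution(items, lam, pmax(1 - lam^2, UNIQUENESS_FLOOR),
                      method = "minres", converged = TRUE,
                      iterations = fit$counts[["function"]],
                      heywood = heywood, discrepancy = fit$value)
}

# squared-multiple-correlation start (as in standard EFA practice); it is
# exactly zero for a diagonal matrix, which keeps degenerate inputs at the
# no-common-factor solution instead of a spurious single-item factor
minres_start <- function(r, bound) {
  eig <- eigen(r, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  smc <- tryCatch(pmax(1 - 1 / diag(solve(r)), 0), error = function(err) NULL)
  off <- r; diag(off) <- 0
  if (is.null(smc) || (max(smc) < 1e-8 && max(abs(off)) > 1e-8)) {
    lam0 <- v1 * sqrt(max(eig$values[1], 0))
  } else {
    lam0 <- sign(v1) * sqrt(pmin(smc, 0.98))
  }
  pmin(pmax(lam0, -0.95 * bound), 0.95 * bound)
}

#' One-factor confirmatory factor analysis by normal-theory ML
#'
#' Minimizes the maximum-likelihood discrepancy
#' `F = log det(Sigma) + tr(S Sigma^-1) - log det(S) - I` over
#' `Sigma = lambda lambda' + diag(psi2)`, with the latent variance fixed at
#' 1. Operates on the covariance metric; omega computed from the solution is
#' scale-free, so it is comparable with the correlation-metric minres omega.
#'
#' @param s Sample covariance matrix (positive definite), I >= 3.
#' @param n Number of observations behind `s` (must exceed I).
#' @return A `factor_solution` tibble; see [factor_minres()].
#' @examples
#' lam <- c(0.5, 0.4, 0.3); psi2 <- c(0.2, 0.25, 0.3)
#' s <- tcrossprod(lam) + diag(psi2)
#' cfa_ml_onefactor(s, n = 1000)
#' @export
cfa_ml_onefactor <- function(s, n) {
  if (!is_square_symmetric(s)) abort("`s` must be a square symmetric matrix.")
  i <- nrow(s)
  if (i < 3) abort("At least 3 items are required for a one-factor solution.")
  if (n <= i) abort("`n` must exceed the number of items.")
  eig_s <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(eig_s) <= 0) abort("`s` must be positive definite for normal-theory ML.")
  logdet_s <- sum(log(eig_s))
  psi_floor <- UNIQUENESS_FLOOR

  unpack <- function(par) list(lam = par[seq_len(i)], psi2 = par[i + seq_len(i)])
  discrepancy <- function(par) {
    p <- unpack(par)
    sig <- tcrossprod(p$lam) + diag(p$psi2, i)
    ch <- tryCatch(chol(sig), error = function(err) NULL)
    if (is.null(ch)) return(1e10)
    sig_inv <- chol2inv(ch)
    2 * sum(log(diag(ch))) + sum(sig_inv * s) - logdet_s - i
  }
  gradient <- function(par) {
    p <- unpack(par)
    sig <- tcrossprod(p$lam) + diag(p$psi2, i)
    ch <- tryCatch(chol(sig), error = function(err) NULL)
    if (is.null(ch)) return(rep(0, 2 * i))
    sig_inv <- chol2inv(ch)
    g_mat <- sig_inv - sig_inv %*% s %*% sig_inv
    c(2 * as.vector(g_mat %*% p$lam), diag(g_mat))
  }

  eig <- eigen(s, symmetric = TRUE)
  lam0 <- eig$vectors[, 1] * sqrt(max(eig$values[1], 0))
  if (sum(lam0) < 0) lam0 <- -lam0
  psi0 <- pmax(diag(s) - lam0^2, 0.1 * diag(s))
  fit <- optim(c(lam0, psi0), discrepancy, gradient, method = "L-BFGS-B",
               lower = c(rep(-Inf, i), rep(psi_floor, i)),
               control = list(maxit = 1000, factr = 1e3))
  if (fit$convergence != 0) {
    abort(sprintf("CFA ML failed to converge: %s", fit$message %||% fit$convergence))
  }
  p <- unpack(fit$par)
  lam <- p$lam
  if (sum(lam) < 0) lam <- -lam
  heywood <- any(abs(p$psi2 - psi_floor) < 1e-10)
  if (heywood) {
    dichrel_note("CFA uniqueness at the lower bound (Heywood case).",
                 class = "dichrel_heywood")
  }
  items <- colnames(s) %||% sprintf("item%02d", seq_len(i))
  new_factor_solution(items, lam, p$psi2,
                      method = "cfa_ml", converged = TRUE,
                      iterations = fit$counts[["function"]],
                      heywood = heywood, discrepancy = fit$value)
}

#' Omega (total) from a one-factor solution
#'
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum psi^2)`: common variance
#' of the sum score over its total model-implied variance.
#'
#' @param solution A `factor_solution`, or a numeric vector of loadings.
#' @param uniqueness Uniquenesses when `solution` is a plain vector.
#' @return Omega in `[0, 1]`.
#' @examples
#' omega_total(rep(0.6, 4), rep(0.64, 4))
#' @export
omega_total <- function(solution, uniqueness = NULL) {
  if (inherits(solution, "factor_solution")) {
    lam <- solution$loading
    psi2 <- solution$uniqueness
  } else {
    lam <- as.numeric(solution)
    psi2 <- as.numeric(uniqueness)
    if (length(psi2) != length(lam)) abort("`uniqueness` must match `solution` in length.")
  }
  common <- sum(lam)^2
  total <- common + sum(psi2)
  if (total <= 0) abort("Degenerate solution: zero total variance.")
  common / total
}
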