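# Sample-based classical coefficients: Cronbach's alpha and the greatest
# lower bound (GLB). Both are functions of the inter-item covariance matrix;
# user-facing entry points accept either raw responses or a covariance
# matrix (a square symmetric input is taken to be one).

#' Sample inter-item covariance matrix
#'
#' Unbiased (n - 1 denominator) covariance of item scores. Constant columns
#' are allowed but flagged, since they carry no reliability information.
#'
#' @param responses Binary response matrix or data frame (persons by items).
#' @return An I x I covariance matrix.
#' @export
covariance_matrix <- function(responses) {
  responses <- as_response_matrix(responses)
  if (nrow(responses) < 2) abort("At least 2 persons are required.")
  s <- stats::cov(responses)
  if (any(diag(s) == 0)) {
    dichrel_note(
      sprintf("%d item(s) have zero variance (constant columns).", sum(diag(s) == 0)),
      class = "dichrel_degenerate"
    )
  }
  s
}

resolve_covariance <- function(x, arg = "x") {
  if (is_square_symmetric(x)) return(x)
  covariance_matrix(x)
}

#' Cronbach's alpha
#'
#' `alpha = I/(I - 1) * (1 - sum(Var(Y_i)) / Var(Y))`, Guttman's lambda-3.
#' Computed from the unbiased sample covariance matrix; accepts either raw
#' responses or a covariance matrix.
#'
#' @param x Binary response matrix/data frame, or an item covariance matrix.
#' @return Alpha (at most 1; can be negative).
#' @examples
#' y <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0), c(0, 0, 0))
#' cronbach_alpha(y)
#' @export
cronbach_alpha <- function(x) {
  s <- resolve_covariance(x)
  i <- nrow(s)
  if (i < 2) abort("At least 2 items are required.")
  var_total <- sum(s)
  if (var_total <= 0) abort("The sum score has zero variance; alpha undefined.")
  (i / (i - 1)) * (1 - sum(diag(s)) / var_total)
}

#' Greatest lower bound to reliability
#'
#' Solves the trace-maximization semidefinite program behind the GLB:
#' maximize `sum(e)` subject to `e >= 0` and `Sigma_Y - diag(e)` positive
#' semidefinite, then returns `1 - sum(e) / Var(Y)` with
#' `Var(Y) = 1' Sigma_Y 1`. The maximal diagonal `e` is the worst-case error
#' variance assignment consistent with a positive semidefinite true-score
#' covariance matrix, hence "greatest lower bound".
#'
#' The program is solved by a log-determinant barrier interior-point method
#' (Newton steps on the length-I vector `e`, barrier parameter increased
#' tenfold per stage) to a duality gap below `tol`. Singular input matrices
#' are handled by deflating the null space: items that load on a null vector
#' must keep zero error variance.
#'
#' @param x Binary response matrix/data frame, or an item covariance matrix.
#' @param tol Target duality gap of the interior-point solve.
#' @return The GLB coefficient in `[0, 1]`.
#' @examples
#' set.seed(1)
#' y <- simulate_responses(rnorm(200), sample_item_parameters(6))
#' glb(y)
#' @export
glb <- function(x, tol = 1e-8) {
  s <- resolve_covariance(x)
  i <- nrow(s)
  if (i < 2) abort("At least 2 items are required.")
  eig <- eigen(s, symmetric = TRUE)
  scale_ref <- mean(diag(s))
  if (min(eig$values) < -1e-8 * scale_ref) {
    abort("Covariance matrix is not positive semidefinite.")
  }
  var_total <- sum(s)
  if (var_total <= 0) abort("The sum score has zero variance; GLB undefined.")

  null_tol <- 1e-10 * max(scale_ref, 1)
  null_idx <- which(eig$values <= null_tol)
  if (length(null_idx) == 0) {
    e <- glb_barrier(s, diag(i), tol = tol)
  } else {
    # null-space deflation: any item with weight on a null vector must have
    # e_i = 0, the rest are optimized in the range-space basis
    nullvec <- eig$vectors[, null_idx, drop = FALSE]
    free <- which(apply(abs(nullvec), 1, max) < 1e-8)
    if (length(free) == 0) return(1)
    u <- eig$vectors[, -null_idx, drop = FALSE]
    s0 <- diag(eig$values[-null_idx], nrow = ncol(u))
    w <- t(u)[, free, drop = FALSE]  # columns: reduced images of unit vectors
    e <- numeric(i)
    e[free] <- glb_barrier(s0, w, tol = tol)
  }
  min(max(1 - sum(e) / var_total, 0), 1)
}

# maximize sum(e) s.t. s0 - sum_j e_j w_j w_j' PSD, e >= 0, where w_j is the
# j-th column of w. For nonsingular input, s0 = S and w = I.
glb_barrier <- function(s0, w, tol = 1e-8) {
  k <- ncol(w)
  scale_ref <- mean(diag(s0))
  s0 <- s0 / scale_ref
  lam_min <- min(eigen(s0, symmetric = TRUE, only.values = TRUE)$values)
  # strictly feasible start: sum_j e w_j w_j' <= e * I because the columns of
  # w are rows of an orthonormal basis, so any uniform e < lambda_min works
  e <- rep(0.5 * lam_min, k)

  a_of <- function(e) s0 - w %*% (e * t(w))
  t_bar <- 1
  mu <- 10
  m_constr <- nrow(s0) + k
  max_stage <- 60
  for (stage in seq_len(max_stage)) {
    # Newton maximization of t*sum(e) + log det A(e) + sum log e
    for (it in 1:80) {
      a <- a_of(e)
      ch <- tryCatch(chol(a), error = function(err) NULL)
      if (is.null(ch)) abort("GLB interior point lost feasibility (numerical failure).")
      b <- crossprod(w, chol2inv(ch) %*% w)  # B = w' A^-1 w
      grad <- t_bar - diag(b) + 1 / e
      hess <- -(b^2) - diag(1 / e^2, k)
      step <- tryCatch(solve(-hess, grad), error = function(err) grad * 0)
      if (all(step == 0)) break
      # backtracking to stay strictly feasible and increase the barrier objective
      alpha <- 1
      f0 <- t_bar * sum(e) + 2 * sum(log(diag(ch))) + sum(log(e))
      repeat {
        e_new <- e + alpha * step
        ok <- all(e_new > 0)
        if (ok) {
          ch_new <- tryCatch(chol(a_of(e_new)), error = function(err) NULL)
          ok <- !is.null(ch_new)
        }
        if (ok) {
          f_new <- t_bar * sum(e_new) + 2 * sum(log(diag(ch_new))) + sum(log(e_new))
          if (f_new >= f0 + 1e-4 * alpha * sum(grad * step)) break
        }
        alpha <- alpha / 2
        if (alpha < 1e-12) break
      }
      if (alpha < 1e-12) break
      decrement <- sum(grad * step)
      e <- e + alpha * step
      if (decrement / 2 < 1e-10) break
    }
    if (m_constr / t_bar < tol) break
    t_bar <- t_bar * mu
    if (stage == max_stage) abort("GLB interior point failed to converge.")
  }
  e * scale_ref
}
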