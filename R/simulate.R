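#' Item characteristic curve of the 2PL model
#'
#' Probability of a correct (1) response given the latent trait:
#' `P(theta) = exp(D a (theta - b)) / (1 + exp(D a (theta - b)))`. With
#' `link = "probit"` the normal-ogive curve `pnorm(a (theta - b))` is used
#' instead (no `D`); the probit variant backs the equivalence between the
#' categorical factor model and the item response formulation.
#'
#' @param theta Numeric vector of latent-trait values (finite).
#' @param bank An [item_bank()].
#' @param link `"logistic"` (default) or `"probit"`.
#'
#' @return A `length(theta) x nrow(bank)` matrix of probabilities.
#' @examples
#' icc(c(-1, 0, 1), item_bank(a = 1, b = 0))
#' @export
icc <- function(theta, bank, link = c("logistic", "probit")) {
  link <- match.arg(link)
  bank <- assert_item_bank(bank)
  if (!is.numeric(theta) || !all(is.finite(theta))) {
    abort("`theta` must be finite numeric.")
  }
  dev <- outer(theta, bank$b, "-")
  if (link == "logistic") {
    eta <- scaling_constant(bank) * sweep(dev, 2, bank$a, "*")
    p <- plogis(eta)
  } else {
    p <- pnorm(sweep(dev, 2, bank$a, "*"))
  }
  colnames(p) <- bank$item
  p
}

#' Sample latent trait scores
#'
#' Standard-normal trait draws: one column when `correlation` is `NULL`, or
#' two columns from a bivariate normal with unit variances and the given
#' population correlation (the two-construct design used to study
#' disattenuation). Uses the session RNG.
#'
#' @param n Number of persons (at least 2).
#' @param correlation `NULL` for a single trait, or a value in (-1, 1) for a
#'   correlated trait pair.
#'
#' @return A numeric matrix with `n` rows and 1 or 2 columns.
#' @examples
#' set.seed(1)
#' head(sample_theta(5, correlation = 0.7))
#' @export
sample_theta <- function(n, correlation = NULL) {
  if (n < 2) abort("`n` must be at least 2.")
  if (is.null(correlation)) {
    return(matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "theta")))
  }
  if (!is.numeric(correlation) || length(correlation) != 1 || abs(correlation) >= 1) {
    abort("`correlation` must be a single value strictly inside (-1, 1).")
  }
  sigma <- matrix(c(1, correlation, correlation, 1), 2)
  th <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = sigma)
  colnames(th) <- c("theta1", "theta2")
  th
}

#' Simulate dichotomous responses from a 2PL item bank
#'
#' Each entry is 1 with probability `icc(theta, item)`, independently across
#' persons and items (one uniform draw per entry). Uses the session RNG.
#'
#' @param theta Numeric vector of person trait values.
#' @param bank An [item_bank()].
#' @param link Passed to [icc()].
#'
#' @return An integer 0/1 matrix, persons by items.
#' @examples
#' set.seed(1)
#' simulate_responses(rnorm(4), item_bank(a = c(0.5, 1), b = c(0, 1)))
#' @export
simulate_responses <- function(theta, bank, link = "logistic") {
  p <- icc(theta, bank, link = link)
  y <- matrix((runif(length(p)) < p) * 1L, nrow = nrow(p),
              dimnames = dimnames(p))
  y
}

#' Unweighted sum score
#'
#' The number-correct score `Y = Y_1 + ... + Y_I` for each person.
#'
#' @param responses Binary response matrix or data frame (persons by items).
#' @return Integer vector of per-person scores in `[0, I]`.
#' @examples
#' sum_score(rbind(c(1, 0, 1), c(0, 0, 0)))
#' @export
sum_score <- function(responses) {
  responses <- as_response_matrix(responses)
  as.integer(rowSums(responses))
}
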