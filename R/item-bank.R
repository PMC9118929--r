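#' Construct a 2PL item bank
#'
#' An item bank is a tibble with one row per item, columns `item`, `a`
#' (discrimination, normal metric, must be positive) and `b` (difficulty, in
#' latent-trait units), plus a bank-level logistic scaling constant `D`
#' carried as an attribute. The same `D` is used everywhere the bank is used
#' (response generation, estimation, reliability formulas) so the metric can
#' never drift between stages. `D = 1.702` makes the logistic curve match the
#' normal-ogive model closely; `D = 1` gives the pure logistic metric.
#'
#' @param a Numeric vector of item discriminations, all `> 0`.
#' @param b Numeric vector of item difficulties, same length as `a`.
#' @param D Logistic scaling constant, a single positive number.
#' @param item Optional item identifiers (defaults to `"item01"`, ...).
#'
#' @return A tibble of class `item_bank` with attribute `D`.
#' @examples
#' bank <- item_bank(a = c(0.6, 1.1), b = c(-0.5, 0.4))
#' scaling_constant(bank)
#' @export
item_bank <- function(a, b, D = 1.702, item = NULL) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 1 || length(a) != length(b)) {
    abort("`a` and `b` must be equal-length vectors with at least one item.")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    abort("Item parameters must be finite.")
  }
  if (any(a <= 0)) {
    abort(sprintf("All discriminations must be positive; item %d has a = %g.",
                  which(a <= 0)[1], a[which(a <= 0)[1]]))
  }
  if (!is.numeric(D) || length(D) != 1 || !is.finite(D) || D <= 0) {
    abort("`D` must be a single positive number.")
  }
  item <- item %||% sprintf("item%02d", seq_along(a))
  out <- tibble(item = as.character(item), a = a, b = b)
  attr(out, "D") <- D
  class(out) <- c("item_bank", class(out))
  out
}

# subsetting keeps the scaling constant and class
#' @export
`[.item_bank` <- function(x, ...) {
  d <- attr(x, "D")
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "D") <- d
    class(out) <- unique(c("item_bank", class(out)))
  }
  out
}

#' @rdname item_bank
#' @param bank An `item_bank`.
#' @export
scaling_constant <- function(bank) {
  attr(bank, "D") %||% 1.702
}

assert_item_bank <- function(bank) {
  if (!inherits(bank, "item_bank")) {
    if (is.data.frame(bank) && all(c("a", "b") %in% names(bank))) {
      return(item_bank(bank$a, bank$b,
                       D = attr(bank, "D") %||% 1.702,
                       item = if ("item" %in% names(bank)) bank$item else NULL))
    }
    abort("Expected an `item_bank` (see `item_bank()`).")
  }
  bank
}

#' Sample 2PL item parameters
#'
#' Draws item discriminations from a lognormal distribution and difficulties
#' from a normal distribution. The defaults, `a ~ logN(-0.75, 0.25^2)` and
#' `b ~ N(0, 0.75^2)`, emulate well-behaved educational test items:
#' discriminations concentrated around 0.5 on the normal metric (about 0.85
#' on the logistic metric once multiplied by `D`) and difficulties spanning
#' roughly two standard deviations of the trait.
#'
#' Draws use the session RNG; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param n_items Number of items to draw.
#' @param a_meanlog,a_sdlog Lognormal log-mean and log-sd for discriminations.
#' @param b_mean,b_sd Normal mean and sd for difficulties.
#' @param D Logistic scaling constant stored in the bank.
#'
#' @return An [item_bank()].
#' @examples
#' set.seed(1)
#' sample_item_parameters(5)
#' @export
sample_item_parameters <- function(n_items,
                                   a_meanlog = -0.75, a_sdlog = 0.25,
                                   b_mean = 0, b_sd = 0.75,
                                   D = 1.702) {
  if (n_items < 1) abort("`n_items` must be at least 1.")
  a <- rlnorm(n_items, meanlog = a_meanlog, sdlog = a_sdlog)
  b <- rnorm(n_items, mean = b_mean, sd = b_sd)
  item_bank(a = a, b = b, D = D)
}
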