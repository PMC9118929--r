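#' Rectangular quadrature grid over the latent trait
#'
#' Equally spaced nodes with renormalized standard-normal density weights,
#' used to evaluate latent-trait integrals by the rectangular rule. The
#' default grid (101 nodes on \[-6, 6\]) reproduces the first two moments of
#' the standard normal to better than 1e-3 and is the grid used to define
#' quadrature ("true") reliability throughout the package.
#'
#' @param nodes Number of nodes (at least 2).
#' @param lower,upper Grid endpoints (both included), `lower < upper`.
#'
#' @return A tibble of class `trait_grid` with columns `x` (node) and `w`
#'   (weight); weights sum to 1.
#' @examples
#' g <- trait_grid()
#' sum(g$w)
#' @export
trait_grid <- function(nodes = 101, lower = -6, upper = 6) {
  if (nodes < 2) abort("`nodes` must be at least 2.")
  if (!(lower < upper)) abort("`lower` must be strictly less than `upper`.")
  x <- seq(lower, upper, length.out = nodes)
  w <- dnorm(x)
  w <- w / sum(w)
  out <- tibble(x = x, w = w)
  class(out) <- c("trait_grid", class(out))
  out
}

assert_trait_grid <- function(grid) {
  if (!inherits(grid, "trait_grid")) {
    if (is.data.frame(grid) && all(c("x", "w") %in% names(grid))) {
      grid <- grid
    } else {
      abort("Expected a `trait_grid` (see `trait_grid()`).")
    }
  }
  if (abs(sum(grid$w) - 1) > 1e-12) abort("Grid weights must sum to 1.")
  grid
}
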