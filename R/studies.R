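# Monte Carlo harnesses. Study 1 benchmarks the two parameter-based
# reliability computations (analytic vs quadrature) through the
# disattenuation formula: if the reliabilities are right, the corrected
# sum-score correlation recovers the known latent correlation. Study 2
# compares all coefficients' RMSE and bias against the per-dataset
# quadrature reliability at the generating parameters.

#' Disattenuate an observed correlation
#'
#' `r / sqrt(rho_xx * rho_yy)`: corrects a correlation between two
#' error-prone sum scores for their unreliability. Values above 1 are
#' possible and returned as-is.
#'
#' @param r_xy Observed correlation(s).
#' @param rho_xx,rho_yy Reliabilities in (0, 1].
#' @return Corrected correlation(s).
#' @examples
#' disattenuate(0.45, 0.81, 0.81)
#' @export
disattenuate <- function(r_xy, rho_xx, rho_yy) {
  if (any(rho_xx <= 0) || any(rho_yy <= 0)) abort("Reliabilities must be positive.")
  r_xy / sqrt(rho_xx * rho_yy)
}

#' Root mean square error and bias of coefficient estimates
#'
#' `rmse = sqrt(mean((estimate - truth)^2))` and
#' `bias = mean(estimate - truth)`; the truth may vary per dataset.
#'
#' @param estimates,truths Equal-length numeric vectors (length >= 1).
#' @return A single value.
#' @examples
#' rmse(c(0.7, 0.9), c(0.8, 0.8))
#' bias(c(0.7, 0.9), c(0.8, 0.8))
#' @export
rmse <- function(estimates, truths) {
  check_metric_args(estimates, truths)
  sqrt(mean((estimates - truths)^2))
}

#' @rdname rmse
#' @export
bias <- function(estimates, truths) {
  check_metric_args(estimates, truths)
  mean(estimates - truths)
}

check_metric_args <- function(estimates, truths) {
  if (length(estimates) < 1 || length(estimates) != length(truths)) {
    abort("`estimates` and `truths` must be equal-length, nonempty vectors.")
  }
}

#' Disattenuation accuracy study
#'
#' For every design cell (true latent correlation x items per construct):
#' draw correlated unit-variance traits for `n_persons`, sample a fresh 2PL
#' item bank per construct, simulate responses, correlate the two sum
#' scores, and disattenuate by the analytic and the quadrature reliabilities
#' computed from the true (generating) parameters. Cell averages of the raw
#' and the two corrected correlations are returned with Monte Carlo standard
#' errors.
#'
#' @param true_correlations Latent correlations to cross (default
#'   .3/.5/.7/.9).
#' @param items_per_construct Test lengths to cross (default 10 to 70 by 5).
#' @param n_persons Persons per dataset (default 500).
#' @param n_reps Replications per cell (default 1000).
#' @param seed Root seed; each cell gets an independent derived seed, so
#'   results do not depend on cell order.
#' @param D Logistic scaling constant used throughout.
#' @param grid Quadrature grid for the quadrature reliabilities.
#' @return A tibble of class `study1_result`, one row per cell x method
#'   (`observed`, `analytic`, `quadrature`): `mean_estimate`, `mc_se`,
#'   `true_correlation`, `n_items`, `n_reps`.
#' @examples
#' run_study1(true_correlations = 0.7, items_per_construct = 10,
#'            n_reps = 20, seed = 1)
#' @export
run_study1 <- function(true_correlations = c(0.3, 0.5, 0.7, 0.9),
                       items_per_construct = seq(10, 70, by = 5),
                       n_persons = 500, n_reps = 1000, seed = 1,
                       D = 1.702, grid = trait_grid()) {
  cells <- tidyr::expand_grid(true_correlation = true_correlations,
                              n_items = items_per_construct)
  res <- purrr::pmap(cells, function(true_correlation, n_items) {
    cell_id <- match(true_correlation, true_correlations) * 1000 +
      match(n_items, items_per_construct)
    set.seed(derive_seed(seed, cell_id))
    est <- matrix(NA_real_, n_reps, 3,
                  dimnames = list(NULL, c("observed", "analytic", "quadrature")))
    for (r in seq_len(n_reps)) {
      ax <- rlnorm(n_items, -0.75, 0.25); bx <- rnorm(n_items, 0, 0.75)
      ay <- rlnorm(n_items, -0.75, 0.25); by <- rnorm(n_items, 0, 0.75)
      th <- sample_theta(n_persons, correlation = true_correlation)
      r_xy <- cor(sumscore_fast(th[, 1], ax, bx, D),
                  sumscore_fast(th[, 2], ay, by, D))
      est[r, ] <- c(
        r_xy,
        disattenuate(r_xy, rel_analytic_fast(ax, bx), rel_analytic_fast(ay, by)),
        disattenuate(r_xy, rel_quad_fast(ax, bx, D, grid$x, grid$w),
                     rel_quad_fast(ay, by, D, grid$x, grid$w))
      )
    }
    tibble(true_correlation = true_correlation, n_items = n_items,
           method = colnames(est),
           mean_estimate = colMeans(est),
           mc_se = apply(est, 2, stats::sd) / sqrt(n_reps),
           n_reps = n_reps)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("study1_result", class(out))
  attr(out, "seed") <- seed
  out
}

#' @export
autoplot.study1_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_items, y = .data$mean_estimate,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$true_correlation),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~true_correlation, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Items per construct", y = "Average estimated correlation",
                  colour = "Method")
}

# full coefficient roster for study 2
STUDY2_COEFFICIENTS <- c("da_true", "dq", "da", "alpha", "glb", "omega", "cfa", "gy")

#' Coefficient comparison study
#'
#' For each cell (test length x sample size), simulates datasets with item
#' parameters redrawn per dataset, computes the requested coefficients, and
#' reports RMSE and bias against the per-dataset true reliability (the
#' quadrature decomposition at the generating parameters). Datasets where a
#' coefficient fails (non-convergence, degenerate items) are dropped for
#' that coefficient and counted.
#'
#' Coefficients: `da_true` (analytic at true parameters), `dq`/`da`
#' (quadrature/analytic at 2PL estimates), `alpha`, `glb`, `omega` (minres
#' on the Pearson correlation matrix), `cfa` (one-factor normal-theory ML on
#' the covariance matrix), `gy` (categorical pipeline).
#'
#' @param n_items_grid Test lengths (default 15, 40, 65).
#' @param n_persons_grid Sample sizes (default 100, 300, 500, 1000, 3000).
#' @param n_reps Replications per cell (default 200).
#' @param coefficients Subset of the roster to compute.
#' @param seed Root seed; per-cell derived seeds as in [run_study1()].
#' @param D Logistic scaling constant.
#' @param grid Quadrature grid defining true reliability.
#' @param config [estimation_config()] for the 2PL fits behind `dq`/`da`.
#' @return A tibble of class `study2_result`, one row per cell x
#'   coefficient: `rmse`, `bias`, their x100 companions (`rmse_x100`,
#'   `bias_x100`), `mc_se_bias`, `n_ok`, `n_failed`.
#' @examples
#' run_study2(n_items_grid = 15, n_persons_grid = 300, n_reps = 5,
#'            coefficients = c("alpha", "glb"), seed = 1)
#' @export
run_study2 <- function(n_items_grid = c(15, 40, 65),
                       n_persons_grid = c(100, 300, 500, 1000, 3000),
                       n_reps = 200,
                       coefficients = STUDY2_COEFFICIENTS,
                       seed = 1, D = 1.702, grid = trait_grid(),
                       config = estimation_config(D = D)) {
  coefficients <- match.arg(coefficients, STUDY2_COEFFICIENTS, several.ok = TRUE)
  cells <- tidyr::expand_grid(n_items = n_items_grid, n_persons = n_persons_grid)
  res <- purrr::pmap(cells, function(n_items, n_persons) {
    cell_id <- 2e6 + match(n_items, n_items_grid) * 100 +
      match(n_persons, n_persons_grid)
    set.seed(derive_seed(seed, cell_id))
    est <- matrix(NA_real_, n_reps, length(coefficients),
                  dimnames = list(NULL, coefficients))
    truth <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      bank <- sample_item_parameters(n_items, D = D)
      th <- rnorm(n_persons)
      y <- simulate_responses(th, bank)
      truth[r] <- reliability_quadrature(bank, grid)$reliability
      est[r, ] <- compute_coefficients(y, coefficients, bank, grid, config)
    }
    purrr::map_dfr(coefficients, function(cf) {
      ok <- is.finite(est[, cf])
      dev <- est[ok, cf] - truth[ok]
      tibble(n_items = n_items, n_persons = n_persons, coefficient = cf,
             n_ok = sum(ok), n_failed = sum(!ok),
             rmse = sqrt(mean(dev^2)), bias = mean(dev),
             rmse_x100 = 100 * sqrt(mean(dev^2)), bias_x100 = 100 * mean(dev),
             mc_se_bias = stats::sd(dev) / sqrt(sum(ok)))
    })
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("study2_result", class(out))
  attr(out, "seed") <- seed
  attr(out, "n_reps") <- n_reps
  out
}

# one dataset -> named coefficient vector (NA on failure), notes muffled
compute_coefficients <- function(y, coefficients, bank, grid, config) {
  out <- stats::setNames(rep(NA_real_, length(coefficients)), coefficients)
  quiet <- function(expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(err) NA_real_),
      dichrel_note = function(w) invokeRestart("muffleWarning")
    )
  }
  if ("da_true" %in% coefficients) {
    out["da_true"] <- quiet(reliability_analytic(bank)$reliability)
  }
  if (any(c("dq", "da") %in% coefficients)) {
    fit <- quiet(estimate_2pl(y, config))
    if (inherits(fit, "item_bank")) {
      if ("dq" %in% coefficients) {
        out["dq"] <- quiet(reliability_quadrature(fit, grid)$reliability)
      }
      if ("da" %in% coefficients) {
        out["da"] <- quiet(reliability_analytic(fit)$reliability)
      }
    }
  }
  if (any(c("alpha", "glb", "cfa") %in% coefficients)) {
    s <- quiet(covariance_matrix(y))
    if (is.matrix(s)) {
      if ("alpha" %in% coefficients) out["alpha"] <- quiet(cronbach_alpha(s))
      if ("glb" %in% coefficients) out["glb"] <- quiet(glb(s))
      if ("cfa" %in% coefficients) {
        out["cfa"] <- quiet(omega_total(cfa_ml_onefactor(s, nrow(y))))
      }
    }
  }
  if ("omega" %in% coefficients) {
    out["omega"] <- quiet({
      r <- stats::cor(y)
      omega_total(factor_minres(r))
    })
  }
  if ("gy" %in% coefficients) {
    out["gy"] <- quiet(reliability_green_yang(y)$reliability)
  }
  out
}

#' @export
autoplot.study2_result <- function(object, metric = c("rmse", "bias"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_persons, y = .data[[metric]],
                               colour = .data$coefficient)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~n_items, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Sample size", y = toupper(metric), colour = "Coefficient")
}
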