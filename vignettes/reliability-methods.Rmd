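---
title: "Reliability of sum scores from dichotomous items: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability of sum scores from dichotomous items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(dichrel)
```

## The problem

Educational and psychological tests built from dichotomously scored items
(correct/incorrect, endorsed/not) are most often summarized by the unweighted
sum score $Y = Y_1 + \dots + Y_I$. Classical reliability of that score is the
ratio of true-score variance to total variance,

$$\rho_{YY} = \frac{\mathrm{Var}(T)}{\mathrm{Var}(T) + \mathrm{Var}(E)},$$

a single number in $[0, 1]$ that users of a test report routinely. For
dichotomous items most reliability methodology was developed for continuous
indicators, and the popular coefficients (alpha, the greatest lower bound,
omega) make assumptions the data may not meet. This package implements, in
one place, the model-based coefficients that take the binary nature of the
items seriously, the classical sample coefficients, and Monte Carlo
harnesses that compare them all under a common data-generating model.

## The data-generating model

Responses follow the two-parameter logistic (2PL) item response model:

$$P_i(\theta) = \frac{\exp[D a_i(\theta - b_i)]}{1 + \exp[D a_i(\theta - b_i)]},$$

with discrimination $a_i > 0$, difficulty $b_i$, standard-normal latent
trait $\theta$, and scaling constant $D$. With $D = 1.702$ the logistic
curve is nearly indistinguishable from the normal-ogive (probit) curve with
slope $a_i$, which is what makes the analytic approximations below and the
categorical factor model exact counterparts of the same model.

**Choice of $D$.** $D$ defaults to 1.702 and is configurable, but it is
carried *inside* the item bank so that generation, estimation, and every
reliability formula always use the same metric. Rescaling $D \to cD$,
$a \to a/c$ leaves all probabilities and all reliabilities unchanged (this
invariance is asserted in the test suite).

**Default parameter distributions.** `sample_item_parameters()` draws
$a \sim \mathrm{logN}(-0.75, 0.25^2)$ (mean $\approx 0.49$ on the normal
metric, i.e. moderate discriminations around $0.83$ after multiplying by
$D$) and $b \sim N(0, 0.75^2)$ (difficulties within about two trait standard
deviations). These are the conditions under which all simulation results in
this package are produced; they emulate a well-constructed unidimensional
achievement test. Real data can of course depart from them —
multidimensionality, guessing, local dependence, and missingness are all
outside this generator, so passing simulations here say nothing about those
violations.

## Parameter-based reliability: quadrature and analytic routes

Given item parameters, the item error variance and the true-score variance
of the sum are one-dimensional integrals over the trait density. The
**quadrature route** (`reliability_quadrature()`) evaluates them by the
rectangular rule on an equally spaced grid with renormalized normal weights,

$$\mathrm{Var}(E_i) \approx \sum_q P_i(X_q)[1 - P_i(X_q)] W_q, \qquad
\mathrm{Var}(T) \approx \sum_q \Big[\sum_i P_i(X_q)\Big]^2 W_q -
\Big[\sum_q \sum_i P_i(X_q) W_q\Big]^2,$$

using 101 nodes on $[-6, 6]$ by default. This grid recovers the first two
moments of the standard normal to better than $10^{-3}$, and refining it to
2001 nodes moves reliability by less than $10^{-6}$ over the sampled
parameter range (both asserted in tests); we therefore treat the 101-node
quadrature value as *the* true reliability implied by a parameter set.

The **analytic route** (`reliability_analytic()`) replaces the integrals
with closed-form approximations: the marginal probability
$\pi_i \approx [1 - \mathrm{erf}(Z_i)]/2$ with
$Z_i = a_i b_i / \sqrt{2(1 + a_i^2)}$ and a four-constant polynomial error
function (absolute error below $5 \times 10^{-4}$), and the item error
variance $m_i \exp[-0.5 (b_i/d_i)^2]$ with quadratic/rational polynomials in
$a_i$. The test true-score variance is assembled as

$$\mathrm{Var}(T) \approx \Big(\sum_i \sqrt{\pi_i(1 - \pi_i) -
\mathrm{Var}(E_i)}\Big)^2,$$

the covariance form implied by perfectly correlated item true scores under a
unidimensional trait. A plain-product form (squaring the sum of the
bracketed terms themselves) is sometimes seen, but it is dimensionally a
squared variance and produces absurdly low values; the square-root form is
the one consistent with the construction and with the observed behaviour of
the approximation (a *mild* overestimate of the quadrature value, confirmed
as a mean property over hundreds of sampled banks in the tests). For extreme
items the bracketed term can go slightly negative under the approximation;
it is clipped at zero and flagged.

```{r}
bank <- item_bank(a = c(0.45, 0.6, 0.85), b = c(-1, 0, 1.2))
glance(reliability_quadrature(bank))
glance(reliability_analytic(bank))
```

## Sample coefficients

**Alpha** (`cronbach_alpha()`) is Guttman's $\lambda_3$ computed from the
unbiased sample covariance matrix. Under item-specific loadings (the
congeneric case that 2PL data with varying $a_i$ produce) it underestimates
reliability; this negative bias is visible in every simulation cell.

**Greatest lower bound** (`glb()`) solves the trace-maximization
semidefinite program: maximize total error variance $\sum_i e_i$ subject to
$e_i \ge 0$ and $\Sigma_Y - \mathrm{diag}(e)$ positive semidefinite, then
$\mathrm{GLB} = 1 - \sum_i e_i / \mathrm{Var}(Y)$ with $\mathrm{Var}(Y) =
\mathbf{1}'\Sigma_Y\mathbf{1}$ (identical to the sample variance of the sum
under the $n-1$ convention). The solver is a log-determinant barrier
interior-point method on the length-$I$ vector $e$ — gradient and Hessian of
$\log\det(\Sigma_Y - \mathrm{diag}(e))$ are available in closed form — run
to a duality gap of $10^{-8}$; singular inputs are handled by deflating the
null space (items loading on a null vector must keep $e_i = 0$, so a rank-1
matrix yields GLB = 1 exactly). Solutions are verified in the tests against
coarse-to-fine brute-force search on $3\times 3$ instances, and the solver
was checked against an independent convex optimizer and Karush-Kuhn-Tucker
certificates during development. An important empirical caveat demonstrated
by the package's own simulations: the *exact* GLB has substantial positive
sampling bias in small samples (on the order of +0.14 at $N = 100$ with 15
items under the default generator), so published GLB simulation values
obtained with other software may be noticeably smaller than what the exact
program produces.

**Omega** (`omega_total()`) is $(\sum_i \lambda_i)^2 / [(\sum_i \lambda_i)^2
+ \sum_i \psi_i^2]$ from a one-factor solution. Two extraction engines are
provided: `factor_minres()` (ordinary least squares on the off-diagonal of
the Pearson correlation matrix, with squared-multiple-correlation starting
values) and `cfa_ml_onefactor()` (normal-theory maximum likelihood on the
covariance matrix, latent variance fixed at 1, analytic gradients). Omega is
scale-free, so the correlation-metric and covariance-metric solutions agree
for the same model; uniquenesses are floored at $10^{-3}$ and solutions at
the bound are flagged as Heywood cases rather than silently repaired.

## Categorical (nonlinear SEM) reliability

The underlying-variable approach treats each item as a dichotomized standard
normal variable: threshold $\tau_i = \Phi^{-1}(P(Y_i = 0))$, pairwise
tetrachoric correlations by two-step maximum likelihood (thresholds fixed
from the margins, one latent correlation per pair maximizing the four-cell
multinomial likelihood), and probit-metric loadings fitted to the
tetrachoric matrix by unweighted least squares. The reliability of the sum
score implied by this model (`green_yang_reliability()`) is the ratio of the
model-implied true-score variance of the sum to its model-implied total
variance, where every covariance entry has the form
$\Phi_2(\tau_i, \tau_j; c) - \Phi(\tau_i)\Phi(\tau_j)$ with $c =
\lambda_i\lambda_j$ in the numerator and the tetrachoric correlation (1 on
the diagonal) in the denominator.

The bivariate normal CDF $\Phi_2$ is evaluated from the single-integral
identity $\Phi_2(h, k, \rho) = \Phi(h)\Phi(k) + \tfrac{1}{2\pi}
\int_0^{\arcsin\rho} \exp[-(h^2 + k^2 - 2hk\sin t)/(2\cos^2 t)]\,dt$ with
fixed Gauss-Legendre nodes; it matches adaptive integration to $10^{-8}$
over the tested range and is fully vectorized, which is what makes the
pairwise tetrachoric matrix cheap even for 65 items (a safeguarded
vectorized bisection on each pair's score function, all pairs advanced
simultaneously).

Because the probit one-factor model *is* the 2PL up to the link function,
the population Green-Yang value with $\lambda_i = a_i/\sqrt{1 + a_i^2}$ and
$\tau_i = \lambda_i b_i$ equals the probit-link quadrature reliability; the
package reproduces this equivalence to $10^{-3}$ (to machine precision at
finer grids), which cross-validates both code paths.

**Estimator choice.** Loadings on the tetrachoric matrix use unweighted
least squares rather than a weighted variant: at the small sample sizes
where the categorical pipeline is most fragile ($N = 100$), weight matrices
estimated from asymptotic variances of tetrachorics are themselves noisy and
destabilize the fit. Empty cells in a pair's $2\times2$ table get a $+0.5$
continuity correction on all four cells (flagged); a strict mode that errors
instead is available on the scalar function. One residual instability is
inherent to the two-step estimator: a pair of items with extreme thresholds
can drive the tetrachoric to the $\pm0.999$ bound, which propagates into a
Heywood loading and an occasional large error in the categorical
coefficient even at large $N$ — in simulation roughly one 15-item dataset
in a hundred at $N = 3000$. This is why the categorical coefficient's RMSE,
unlike that of the other model-based coefficients, is not guaranteed to
shrink monotonically with sample size.

## 2PL estimation

`estimate_2pl()` is a marginal maximum likelihood (Bock-Aitkin EM)
estimator: the E-step posterior-weights each person over an estimation grid
(61 equally spaced nodes on $[-6, 6]$ by default — the coarser grid is
standard practice for estimation, while reliability evaluation keeps its own
101-node grid), and the M-step solves one weighted logistic Newton-Raphson
per item. Convergence is declared when the largest parameter change in a
cycle falls below $10^{-4}$ (at most 500 cycles); the marginal
log-likelihood trace is stored and is nondecreasing. Starting values are a
common moderate slope ($0.851/D$) and difficulties from probit-transformed
proportions.

The default is pure maximum likelihood. An optional weak
$\mathrm{logN}(-0.75, 1)$ prior on each discrimination (gated to $n < 300$
with `prior = "auto"`, always flagged) is available to tame the occasional
slope blow-up in very small samples, but it is *not* the default for a
measured reason: the penalized mode sits at $e^{-1.75} \approx 0.17$, well
below typical discriminations, and in simulation at $N = 100$ with 15 items
the prior depressed quadrature reliability at the estimates by about 0.06 on
average, while pure ML was nearly unbiased (at the cost of roughly 9% of
datasets failing to converge — those fits error out and the study harness
drops and counts them, which is the package's general failure policy).
Model-based reliability at the estimates (`estimated_reliability()`) simply
composes the estimator with either parameter-based formula.

## The two study harnesses

`run_study1()` checks the two parameter-based computations *as definitions
of reliability*: simulate two correlated traits
($r \in \{.3, .5, .7, .9\}$), two freshly sampled banks of $I \in \{10,
\dots, 70\}$ items, $N = 500$ persons; correlate the sum scores and
disattenuate by $\hat r / \sqrt{\rho_{XX}\rho_{YY}}$ using reliabilities
computed from the *true* parameters. If the reliability formula is right,
the corrected correlation recovers the truth. The quadrature route does
(maximum cell deviation at or below the .006 level), while the analytic
route undercorrects (e.g. to about .65 in the $r = .7$, 10-item cell) —
i.e. it overestimates reliability mildly.

`run_study2()` compares all eight coefficients (`da_true`, `dq`, `da`,
`alpha`, `glb`, `omega`, `cfa`, `gy`) against the per-dataset quadrature
true reliability, reporting RMSE and bias (raw and $\times 100$) with Monte
Carlo standard errors and per-coefficient failure counts (failed fits are
dropped for that coefficient and counted, never imputed). Default
replication counts are 1000 per cell for the disattenuation study and 200
per cell for the coefficient comparison; both are configurable upward. In
the package's acceptance checks the full-roster comparison is run at the 15
item length (where the top-three RMSE ordering among `dq`, `omega`, `cfa`
is asserted) and the alpha/GLB bias signs are additionally checked at 40 and
65 items; these problem sizes keep the whole suite comfortably reproducible
on a single CPU.

```{r, fig.width = 6, fig.height = 4}
res <- run_study1(true_correlations = 0.7, items_per_construct = c(10, 25, 40),
                  n_reps = 100, seed = 7)
autoplot(res)
```

## Numerical choices and degenerate inputs

* Grid weights always renormalize to sum exactly 1; both endpoints are
  included.
* `reliability_from_variances()` errors when both variances are zero rather
  than returning 0/0.
* Items with no response variation: `thresholds()` and `estimate_2pl()`
  error naming the item; `covariance_matrix()` flags but proceeds (alpha and
  GLB remain defined).
* Ties in simulated responses are impossible almost surely (one uniform
  draw per entry, `u < P` scored 1).
* Tetrachorics are confined to $[-0.999, 0.999]$; boundary solutions are
  returned at the bound.
* Sample Pearson covariance/correlation matrices of complete binary data are
  positive semidefinite by construction, so no smoothing is applied anywhere;
  the GLB solver rejects non-PSD input rather than repairing it.
* All randomness flows through R's session RNG; the study harnesses take a
  root seed and derive an independent 31-bit seed per design cell, so any
  cell can be reproduced in isolation and results do not depend on the order
  cells are run.

## Known limitations

* Unidimensional, locally independent, complete data only; no 1PL/3PL or
  polytomous models; no weighted composites.
* The analytic route's error-variance polynomials have an unstated validity
  range; for discriminations far outside the sampled range the clipping
  safeguard engages more often.
* The exact-GLB small-sample bias noted above means GLB comparisons against
  results produced by approximate GLB implementations need care.
* No parallel execution: per-cell seeding makes it trivial to shard by hand,
  and single-CPU runtimes of the default designs are minutes, not hours.
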