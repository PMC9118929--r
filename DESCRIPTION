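Package: dichrel
Title: Reliability Coefficients for Dichotomously Scored Test Items
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Classical reliability of unweighted sum scores built from
    dichotomously scored items. Implements model-based coefficients
    derived from the two-parameter logistic item response model (an
    analytic error-function approximation and a rectangular-quadrature
    evaluation of the true-score and error-variance integrals), the
    classical sample coefficients alpha and the greatest lower bound
    (solved as a semidefinite trace-maximization program), omega from
    minres exploratory and maximum-likelihood confirmatory one-factor
    solutions, and the categorical (threshold / tetrachoric) nonlinear-SEM
    reliability coefficient. Includes a 2PL response simulator, a
    marginal maximum likelihood (Bock-Aitkin EM) 2PL estimator, and Monte
    Carlo harnesses that benchmark the coefficients by disattenuation
    accuracy and by root mean square error and bias against quadrature
    true reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
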