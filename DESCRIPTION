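Package: relicred
Title: Bayesian Single-Test Reliability Analysis
Version: 0.1.0
Authors@R:
    person("relicred", "developers", email = "relicred@example.org",
           role = c("aut", "cre"))
Description: Posterior distributions, point estimates, highest-posterior-density
    credible intervals and interval probabilities for five single-test
    reliability coefficients: McDonald's omega, Cronbach's alpha, Guttman's
    lambda2 and lambda6, and the greatest lower bound (glb). Classical-test-
    theory coefficients are sampled through the conjugate inverse-Wishart
    posterior of the item covariance matrix; omega through a Gibbs sampler for
    the unidimensional factor model. Includes if-item-dropped analysis,
    Gelman-Rubin convergence diagnostics, a posterior-predictive eigenvalue
    check, Bayesian fit measures (BRMSEA, BCFI, BTLI, BLR), Bayesian imputation
    of missing responses, deterministic synthetic-data generators, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
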