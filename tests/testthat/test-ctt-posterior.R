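test_that("posterior covariance draws are conjugate and reproducible", {
  d <- make_unidimensional(n = 60, k = 3, target_omega = .75, seed = 2)
  mc <- quick_mcmc()
  cd1 <- posterior_cov_draws(d, mcmc = mc, seed = 99)
  cd2 <- posterior_cov_draws(d, mcmc = mc, seed = 99)
  expect_identical(cd1$draws, cd2$draws)
  expect_equal(dim(cd1$draws), c(3, 3, mc$kept, mc$chains))

  # consistency: with many draws the posterior mean approaches the
  # closed-form inverse-Wishart mean (scale / (df_post - k - 1))
  x <- complete_rows(d)
  C <- crossprod(scale(x, center = TRUE, scale = FALSE))
  scale_post <- 1e-10 * diag(3) + C
  df_post <- 3 + nrow(x) - 1
  big <- posterior_cov_draws(d, mcmc = mcmc_config(chains = 1,
                                                   iterations = 8000,
                                                   burn_in = 0), seed = 5)
  m <- apply(big$draws, c(1, 2), mean)
  expect_equal(unname(m), unname(scale_post / (df_post - 3 - 1)),
               tolerance = .05)
})

test_that("prior df below k is rejected", {
  d <- make_unidimensional(n = 20, k = 4, target_omega = .7, seed = 1)
  expect_error(posterior_cov_draws(d, ctt_prior(df = 2)), "df must be")
  expect_error(prior_coefficient_draws(4, ctt_prior(df = 3), 10), "df must be")
})

test_that("coefficient chains map draws through the estimators", {
  # degenerate chain: every draw the same matrix -> constant chains
  cd <- structure(list(draws = array(toy2, c(2, 2, 10, 2)), k = 2,
                       item_names = c("a", "b"), mcmc = quick_mcmc()),
                  class = "cov_draws")
  cc <- ctt_coefficient_chains(cd, c("alpha", "lambda2", "lambda6"))
  expect_equal(unique(as.numeric(cc$alpha$draws)), 2 / 3, tolerance = 1e-12)
  expect_equal(unique(as.numeric(cc$lambda6$draws)), 0.5, tolerance = 1e-12)
  expect_equal(dim(cc$alpha$draws), c(2, 10))

  # ordering holds draw by draw on real posterior samples
  d <- make_unidimensional(n = 80, k = 5, target_omega = .8, seed = 7)
  cd2 <- posterior_cov_draws(d, mcmc = quick_mcmc(), seed = 3)
  cc2 <- ctt_coefficient_chains(cd2, c("alpha", "lambda2", "glb"))
  expect_true(all(cc2$alpha$draws <= cc2$lambda2$draws + 1e-12))
  expect_true(all(cc2$lambda2$draws <= cc2$glb$draws + 1e-6))
})

test_that("prior coefficient draws exist, are finite, and ignore n", {
  p <- prior_coefficient_draws(5, n_draws = 500, seed = 4)
  for (coefficient in names(p)) {
    expect_length(p[[coefficient]], 500)
    expect_true(all(is.finite(p[[coefficient]])))
  }
  expect_true(all(p$glb >= 0 & p$glb <= 1))
  pr <- prob_in_interval(p$alpha, .7, .9)
  expect_true(pr >= 0 && pr <= 1)
  # the prior involves no data: same seed, same draws, whatever n was
  p2 <- prior_coefficient_draws(5, n_draws = 500, seed = 4)
  expect_identical(p, p2)
})

test_that("conditional-normal imputation step matches the closed form", {
  sigma <- matrix(c(1, .9, .9, 1), 2)
  mu <- c(0, 0)
  # observe x1 = 1: x2 | x1 ~ N(.9, .19)
  set.seed(8)
  draws <- replicate(10000, impute_missing_step(c(1, NA), c(TRUE, FALSE),
                                                sigma, mu)[2])
  expect_lt(abs(mean(draws) - .9), .015)   # ~3.4 SE of the mean
  expect_lt(abs(var(draws) - .19), .01)

  # zero correlation: the observed cell is ignored
  sigma0 <- diag(2)
  set.seed(9)
  obs <- runif(5000, -2, 2)
  imp <- vapply(obs, function(o)
    impute_missing_step(c(o, NA), c(TRUE, FALSE), sigma0, mu)[2], numeric(1))
  expect_lt(abs(cor(obs, imp)), .05)

  # complete row unchanged; fully missing row refused
  expect_identical(impute_missing_step(c(1, 2), c(TRUE, TRUE), sigma, mu),
                   c(1, 2))
  expect_error(impute_missing_step(c(NA, NA), c(FALSE, FALSE), sigma, mu),
               "fully missing")
})

test_that("listwise and imputation agree on complete data at equal seeds", {
  d <- make_unidimensional(n = 50, k = 4, target_omega = .75, seed = 12)
  mc <- quick_mcmc()
  a <- posterior_cov_draws(d, mcmc = mc, seed = 42,
                           missing_strategy = "listwise")
  b <- posterior_cov_draws(d, mcmc = mc, seed = 42,
                           missing_strategy = "bayes_impute")
  expect_identical(a$draws, b$draws)
})

test_that("imputation-based alpha tracks the complete-data alpha (10% MCAR)", {
  full <- make_unidimensional(n = 500, k = 5, target_omega = .8, seed = 13)
  holes <- inject_missing(full, rate = .10, seed = 14)
  mc <- quick_mcmc(chains = 2L, iterations = 400L)
  cc_full <- ctt_coefficient_chains(
    posterior_cov_draws(full, mcmc = mc, seed = 1), "alpha")$alpha
  cc_imp <- ctt_coefficient_chains(
    posterior_cov_draws(holes, mcmc = mc, seed = 1,
                        missing_strategy = "bayes_impute"), "alpha")$alpha
  expect_lt(abs(point_estimate(cc_imp) - point_estimate(cc_full)), 0.03)
})

test_that("HPD width shrinks with n on fixed-Sigma synthetic data", {
  widths <- vapply(c(50, 200, 1000), function(n) {
    d <- make_unidimensional(n = n, k = 5, target_omega = .8, seed = 20)
    cc <- ctt_coefficient_chains(
      posterior_cov_draws(d, mcmc = quick_mcmc(), seed = 2), "alpha")$alpha
    h <- hpd_interval(cc)
    h$upper - h$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})
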