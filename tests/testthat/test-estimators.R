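test_that("closed-form coefficients match hand-derived toy values", {
  # 2-item, rho = .5
  expect_equal(cronbach_alpha(toy2), 2 / 3, tolerance = 1e-10)
  expect_equal(guttman_lambda2(toy2), 2 / 3, tolerance = 1e-10)
  expect_equal(guttman_lambda6(toy2), 0.5, tolerance = 1e-10)
  expect_equal(glb(toy2), 2 / 3, tolerance = 1e-7)
  # 3-item compound symmetric, rho = .5
  expect_equal(cronbach_alpha(toy3), 0.75, tolerance = 1e-10)
  expect_equal(guttman_lambda2(toy3), 0.75, tolerance = 1e-10)
  expect_equal(guttman_lambda6(toy3), 2 / 3, tolerance = 1e-10)
  expect_equal(glb(toy3), 0.75, tolerance = 1e-7)
  # diagonal: no shared variance at all
  for (k in c(2, 4, 7)) {
    expect_equal(cronbach_alpha(diag(k)), 0)
    expect_equal(guttman_lambda2(diag(k)), 0)
    expect_equal(guttman_lambda6(diag(k)), 0)
    expect_equal(glb(diag(k)), 0, tolerance = 1e-7)
  }
})

test_that("estimator input validation", {
  expect_error(cronbach_alpha(matrix(c(1, .5, .4, 1), 2)), "symmetric")
  neg <- matrix(c(1, 2, 2, 1), 2)      # eigenvalues 3, -1
  expect_error(cronbach_alpha(neg), "positive semidefinite")
  # singular sigma: lambda6 fails loudly, no silent ridging
  sing <- matrix(1, 3, 3)
  expect_error(guttman_lambda6(sing), "singular")
  expect_error(cronbach_alpha(diag(0, 2)), "degenerate")
})

test_that("omega from factor parameters", {
  expect_equal(omega_from_params(rep(1 / sqrt(2), 3), rep(.5, 3), 1), 0.75,
               tolerance = 1e-10)
  expect_equal(omega_from_params(rep(2 / 3, 5), rep(5 / 9, 5), 1), 0.8,
               tolerance = 1e-12)
  expect_equal(omega_from_params(c(.5, .5), rep(1e-12, 2), 1), 1,
               tolerance = 1e-9)
  expect_equal(omega_from_params(c(0, 0), c(.5, .5), 1), 0)
  expect_error(omega_from_params(c(1, 1), c(.5, -1), 1), "> 0")
})

test_that("item-rest correlation", {
  expect_equal(item_rest_correlation(toy2, 1), 0.5, tolerance = 1e-12)
  expect_equal(item_rest_correlation(toy3, 1), 1 / sqrt(3),
               tolerance = 1e-12)
  expect_equal(item_rest_correlation(diag(4), 2), 0)
})

test_that("sample covariance matches direct summation", {
  d <- item_data(matrix(c(0, 1, 0, 1, 0, 0, 1, 1), 4, 2))
  # brute-force oracle: direct (n-1)-denominator summation
  brute <- function(x) {
    xc <- sweep(x, 2, colMeans(x))
    crossprod(xc) / (nrow(x) - 1)
  }
  expect_equal(sample_covariance(d), brute(d$values), ignore_attr = TRUE)
  d2 <- item_data(matrix(c(0, 1, 0, 1), 2, 2))
  expect_equal(unname(sample_covariance(d2)), matrix(.5, 2, 2))
  d3 <- item_data(matrix(c(2, 2, 3, 3), 2, 2))
  expect_equal(unname(sample_covariance(d3)), matrix(0, 2, 2))
  # listwise view: incomplete rows do not contribute
  m <- matrix(rnorm(20), 10, 2)
  m2 <- rbind(m, c(NA, 99), c(99, NA))
  expect_equal(sample_covariance(item_data(m2)),
               brute(m), ignore_attr = TRUE)
})

test_that("glb agrees with a brute-force grid search for k = 2", {
  set.seed(11)
  for (r in 1:5) {
    v <- runif(2, .5, 2)
    rho <- runif(1, -.8, .8)
    S <- diag(sqrt(v)) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sqrt(v))
    S <- (S + t(S)) / 2
    th <- expand.grid(t1 = seq(0, v[1], .005), t2 = seq(0, v[2], .005))
    feas <- (v[1] - th$t1) * (v[2] - th$t2) >= S[1, 2]^2
    brute <- 1 - max(th$t1[feas] + th$t2[feas]) / sum(S)
    expect_lt(abs(glb(S) - brute), 1e-2)
  }
})

test_that("lower-bound ordering alpha <= lambda2 <= glb on random psd", {
  set.seed(21)
  for (r in 1:200) {
    S <- random_psd(sample(2:8, 1))
    a <- cronbach_alpha(S)
    l2 <- guttman_lambda2(S)
    g <- glb(S)
    expect_true(a <= l2 + 1e-12)
    expect_true(l2 <= g + 1e-6)
    expect_true(g <= 1 && g >= 0)
  }
})

test_that("parallel items: alpha = lambda2 = glb = omega of matching model", {
  # compound symmetry with positive correlation = one-factor, equal loadings
  for (k in c(3, 5)) {
    rho <- .4
    S <- matrix(rho, k, k); diag(S) <- 1
    om <- omega_from_params(rep(sqrt(rho), k), rep(1 - rho, k), 1)
    expect_equal(cronbach_alpha(S), om, tolerance = 1e-6)
    expect_equal(guttman_lambda2(S), om, tolerance = 1e-6)
    expect_equal(glb(S), om, tolerance = 1e-6)
  }
})

test_that("coefficients are invariant under simultaneous rescaling c^2*Sigma", {
  set.seed(31)
  S <- random_psd(5) + diag(5) * .1
  for (f in list(cronbach_alpha, guttman_lambda2, guttman_lambda6, glb)) {
    expect_equal(f(4 * S), f(S), tolerance = 1e-6)
    expect_equal(f(S / 100), f(S), tolerance = 1e-6)
  }
})
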