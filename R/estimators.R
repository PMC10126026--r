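#' Reliability coefficients on a covariance matrix
#'
#' The deterministic core of the package: each classical-test-theory (CTT)
#' coefficient is a function of a symmetric positive-semidefinite item
#' covariance matrix Sigma, and McDonald's omega is a function of
#' single-factor model parameters. The Bayesian machinery maps these
#' functions over posterior draws.
#'
#' @name estimators
NULL

check_covariance <- function(sigma, need_k2 = TRUE) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma)) stop("sigma must be square")
  if (need_k2 && nrow(sigma) < 2L) stop("sigma must be at least 2 x 2")
  if (max(abs(sigma - t(sigma))) > 1e-10 * max(1, max(abs(sigma))))
    stop("sigma is not symmetric (tolerance 1e-10)")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev, 0))
    stop("sigma is not positive semidefinite")
  sigma
}

#' @describeIn estimators Cronbach's alpha:
#'   `k/(k-1) * (1 - trace(Sigma)/sum(Sigma))`. A lower bound to reliability;
#'   at most 1, possibly negative.
#' @param sigma symmetric positive-semidefinite covariance matrix.
#' @export
cronbach_alpha <- function(sigma) {
  sigma <- check_covariance(sigma)
  k <- nrow(sigma)
  tot <- sum(sigma)
  if (tot <= 0) stop("degenerate input: total variance sum(sigma) <= 0")
  k / (k - 1) * (1 - sum(diag(sigma)) / tot)
}

#' @describeIn estimators Guttman's lambda2: alpha's root-sum-of-squares
#'   refinement, at least as large as alpha on every valid input.
#' @export
guttman_lambda2 <- function(sigma) {
  sigma <- check_covariance(sigma)
  k <- nrow(sigma)
  tot <- sum(sigma)
  if (tot <= 0) stop("degenerate input: total variance sum(sigma) <= 0")
  off2 <- sum(sigma^2) - sum(diag(sigma)^2)
  (tot - sum(diag(sigma)) + sqrt(k / (k - 1) * off2)) / tot
}

#' @describeIn estimators Guttman's lambda6: one minus the summed residual
#'   variances of each item regressed on all others, over total variance.
#'   Requires an invertible Sigma; no automatic ridging is applied.
#' @export
guttman_lambda6 <- function(sigma) {
  sigma <- check_covariance(sigma)
  tot <- sum(sigma)
  if (tot <= 0) stop("degenerate input: total variance sum(sigma) <= 0")
  inv <- tryCatch(solve(sigma), error = function(e) {
    stop("sigma is singular; lambda6 needs an invertible covariance matrix. ",
         "Inspect the data rather than regularizing.", call. = FALSE)
  })
  1 - sum(1 / diag(inv)) / tot
}

#' @describeIn estimators Greatest lower bound (glb): the smallest reliability
#'   consistent with Sigma under a psd true-score constraint, found by
#'   maximizing the total error variance `sum(theta)` subject to
#'   `Sigma - diag(theta)` psd and `0 <= theta_i <= sigma_ii` (an SDP solved
#'   by ADMM). Values lie in `[0, 1]` and dominate lambda2.
#' @param tol certified suboptimality of the interior-point solver
#'   (scale-free; Sigma is internally rescaled to unit mean diagonal).
#' @param max_iter Newton-step cap for the solver.
#' @export
glb <- function(sigma, tol = 1e-8, max_iter = 10000L) {
  sigma <- check_covariance(sigma)
  if (mean(diag(sigma)) <= 0) stop("degenerate input: zero total variance")
  res <- .glb_solve(sigma, tol = tol, max_iter = as.integer(max_iter))
  if (!res$converged) {
    stop(sprintf(paste0("glb solver did not converge: %d Newton steps, ",
                        "barrier parameter %.3g (target %.3g)"),
                 res$iterations, res$mu_final, tol / (3 * nrow(sigma))))
  }
  min(max(res$value, 0), 1)
}

#' @describeIn estimators McDonald's omega from single-factor parameters:
#'   `(sum(loadings))^2 * phi / ((sum(loadings))^2 * phi + sum(resid_var))`.
#' @param loadings k-vector of factor loadings.
#' @param resid_var k-vector of positive residual variances.
#' @param phi positive latent variance (default 1).
#' @export
omega_from_params <- function(loadings, resid_var, phi = 1) {
  if (any(resid_var <= 0)) stop("residual variances must be > 0")
  if (phi <= 0) stop("latent variance must be > 0")
  num <- sum(loadings)^2 * phi
  num / (num + sum(resid_var))
}

#' @describeIn estimators Item-rest correlation (corrected item-total
#'   correlation) of item `i` computed from Sigma.
#' @param i item index.
#' @export
item_rest_correlation <- function(sigma, i) {
  sigma <- check_covariance(sigma)
  k <- nrow(sigma)
  if (i < 1 || i > k) stop("item index out of range")
  rest <- setdiff(seq_len(k), i)
  cov_ir <- sum(sigma[i, rest])
  var_rest <- sum(sigma[rest, rest])
  if (var_rest <= 0) stop("rest-sum variance is zero")
  cov_ir / sqrt(sigma[i, i] * var_rest)
}

#' @describeIn estimators Unbiased (n - 1 denominator) sample covariance of
#'   the listwise-complete rows of an [item_data] object.
#' @param data an [item_data] object.
#' @export
sample_covariance <- function(data) {
  x <- complete_rows(data)
  if (nrow(x) < 2L) stop("fewer than 2 complete rows")
  stats::cov(x)
}
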