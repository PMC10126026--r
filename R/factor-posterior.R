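#' Gibbs sampler for the unidimensional factor model
#'
#' Model: `x_i = lambda * f_i + e_i` with latent scores `f_i ~ N(0, phi)` and
#' residuals `e_i ~ N(0, diag(psi))`; the data are column-centered internally
#' (intercepts are not modeled — reliability depends only on the covariance
#' structure). Full conditionals are cycled in a fixed order (scores,
#' loadings, residual variances, latent variance); a reflection step flips
#' all loadings and scores whenever `sum(lambda) < 0`, so the loading tables
#' have a single sign convention while omega is unaffected. With
#' `missing_strategy = "bayes_impute"`, missing cells are redrawn from
#' `N(lambda_j * f_i, psi_j)` every iteration (data augmentation).
#'
#' @param data an [item_data] object.
#' @param prior a [factor_prior].
#' @param mcmc an [mcmc_config].
#' @param seed integer seed.
#' @param missing_strategy `"listwise"` or `"bayes_impute"`.
#' @return object of class `factor_draws`: `loadings` (`chains x kept x k`),
#'   `resid_var` (`chains x kept x k`), `latent_var` and `omega`
#'   (`chains x kept`), plus `k`, `n`, `item_names`, `mcmc`,
#'   `n_floored` (count of variance draws floored at 1e-12).
#' @export
gibbs_factor_sampler <- function(data, prior = factor_prior(),
                                 mcmc = mcmc_config(), seed = 1L,
                                 missing_strategy = c("listwise",
                                                      "bayes_impute")) {
  stopifnot(inherits(data, "item_data"))
  missing_strategy <- match.arg(missing_strategy)
  k <- data$k
  s0 <- if (is.null(prior$latent_scale)) k else prior$latent_scale
  nu0 <- if (is.null(prior$latent_df)) k + 2 else prior$latent_df
  a0 <- prior$resid_shape; b0 <- prior$resid_scale
  mu_l <- prior$loading_mean; sd_l <- prior$loading_sd

  has_missing <- any(!data$mask)
  impute <- missing_strategy == "bayes_impute" && has_missing
  if (impute) {
    keep_row <- rowSums(data$mask) > 0L
    if (any(!keep_row))
      warning(sum(!keep_row), " fully missing row(s) excluded")
    x_raw <- data$values[keep_row, , drop = FALSE]
    mask <- data$mask[keep_row, , drop = FALSE]
    col_means <- colMeans(x_raw, na.rm = TRUE)
    x0 <- sweep(x_raw, 2, col_means)   # centered; NA where missing
    miss_idx <- which(!mask)
  } else {
    xc <- complete_rows(data)
    if (nrow(xc) < 2L) stop("fewer than 2 complete rows")
    x0 <- scale(xc, center = TRUE, scale = FALSE)
    mask <- NULL
  }
  n <- nrow(x0)

  set.seed(seed)
  loadings <- array(NA_real_, c(mcmc$chains, mcmc$kept, k))
  resid_var <- array(NA_real_, c(mcmc$chains, mcmc$kept, k))
  latent_var <- matrix(NA_real_, mcmc$chains, mcmc$kept)
  n_floored <- 0L

  for (ch in seq_len(mcmc$chains)) {
    # dispersed starting values drawn from the prior
    psi <- pmin(1 / stats::rgamma(k, shape = a0, rate = b0), 1e6)
    lam <- stats::rnorm(k, mu_l, sd_l)
    phi <- (s0 / 2) / stats::rgamma(1, shape = nu0 / 2)
    x <- x0
    if (impute) x[miss_idx] <- 0   # start missing cells at item means

    kept_i <- 0L
    for (it in seq_len(mcmc$iterations)) {
      # scores | rest
      prec_f <- 1 / phi + sum(lam^2 / psi)
      f <- drop(x %*% (lam / psi)) / prec_f +
        stats::rnorm(n) / sqrt(prec_f)

      # loadings | rest
      sf2 <- sum(f^2)
      prec_l <- sf2 / psi + 1 / sd_l^2
      lam <- (drop(crossprod(x, f)) / psi + mu_l / sd_l^2) / prec_l +
        stats::rnorm(k) / sqrt(prec_l)

      # residual variances | rest
      resid <- x - tcrossprod(f, lam)
      ss <- colSums(resid^2)
      psi <- 1 / stats::rgamma(k, shape = a0 + n / 2, rate = b0 + ss / 2)
      if (any(psi < 1e-12)) {
        n_floored <- n_floored + sum(psi < 1e-12)
        psi <- pmax(psi, 1e-12)
      }

      # latent variance | rest
      phi <- (s0 + sf2) / 2 / stats::rgamma(1, shape = (nu0 + n) / 2)
      phi <- max(phi, 1e-12)

      # reflection fix
      if (sum(lam) < 0) { lam <- -lam; f <- -f }

      # impute missing cells | rest
      if (impute) {
        fit <- tcrossprod(f, lam)
        noise <- matrix(stats::rnorm(n * k), n, k) *
          rep(sqrt(psi), each = n)
        x[miss_idx] <- (fit + noise)[miss_idx]
      }

      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
        kept_i <- kept_i + 1L
        if (kept_i <= mcmc$kept) {
          loadings[ch, kept_i, ] <- lam
          resid_var[ch, kept_i, ] <- psi
          latent_var[ch, kept_i] <- phi
        }
      }
    }
  }
  if (n_floored > 0L)
    warning(n_floored, " residual-variance draw(s) floored at 1e-12")

  num <- apply(loadings, c(1, 2), sum)^2 * latent_var
  omega <- num / (num + apply(resid_var, c(1, 2), sum))

  structure(list(loadings = loadings, resid_var = resid_var,
                 latent_var = latent_var, omega = omega, k = k, n = n,
                 item_names = data$item_names, mcmc = mcmc,
                 n_floored = n_floored),
            class = "factor_draws")
}

#' @export
print.factor_draws <- function(x, ...) {
  cat(sprintf("factor_draws: %d items, %d chain(s) x %d kept draws\n",
              x$k, dim(x$loadings)[1], dim(x$loadings)[2]))
  invisible(x)
}

#' Omega chain from factor draws
#'
#' @param draws a `factor_draws` object.
#' @return a `coef_chains` object (chains x kept).
#' @export
omega_chain <- function(draws) {
  stopifnot(inherits(draws, "factor_draws"))
  coef_chains("omega", draws$omega)
}

#' Model-implied covariance matrix of one factor draw
#'
#' `Sigma(theta) = phi * lambda %*% t(lambda) + diag(psi)`.
#'
#' @param loadings k-vector of loadings.
#' @param resid_var k-vector of residual variances.
#' @param phi latent variance.
#' @return k x k covariance matrix.
#' @export
implied_covariance <- function(loadings, resid_var, phi = 1) {
  phi * tcrossprod(loadings) + diag(resid_var, nrow = length(loadings))
}

#' Standardized factor loadings
#'
#' Per draw, item j's standardized loading is
#' `lambda_j * sqrt(phi) / sqrt(phi * lambda_j^2 + psi_j)` — invariant to the
#' scale split between phi and the loadings, which is not identified.
#'
#' @param draws a `factor_draws` object.
#' @param estimate `"mean"` or `"median"` posterior summary.
#' @return named k-vector of summarized standardized loadings.
#' @export
standardized_loadings <- function(draws, estimate = c("mean", "median")) {
  stopifnot(inherits(draws, "factor_draws"))
  estimate <- match.arg(estimate)
  k <- draws$k
  out <- numeric(k)
  phi <- draws$latent_var
  for (j in seq_len(k)) {
    lam <- draws$loadings[, , j]
    psi <- draws$resid_var[, , j]
    std <- lam * sqrt(phi) / sqrt(phi * lam^2 + psi)
    out[j] <- if (estimate == "mean") mean(std) else stats::median(std)
  }
  names(out) <- draws$item_names
  out
}

#' Draws of omega under the factor-model prior
#'
#' Samples loadings, residual variances and the latent variance from the
#' prior and maps them through omega. The induced prior is not uniform on
#' the unit interval; with the defaults it places little mass near 1.
#'
#' @param k number of items.
#' @param prior a [factor_prior].
#' @param n_draws number of draws (>= 10000 recommended for tail
#'   probabilities).
#' @param seed integer seed.
#' @return numeric vector of omega draws in the unit interval.
#' @export
prior_omega_draws <- function(k, prior = factor_prior(), n_draws = 100000L,
                              seed = 1L) {
  set.seed(seed)
  s0 <- if (is.null(prior$latent_scale)) k else prior$latent_scale
  nu0 <- if (is.null(prior$latent_df)) k + 2 else prior$latent_df
  lam_sum <- rowSums(matrix(stats::rnorm(n_draws * k, prior$loading_mean,
                                         prior$loading_sd), n_draws, k))
  psi_sum <- rowSums(matrix(1 / stats::rgamma(n_draws * k,
                                              shape = prior$resid_shape,
                                              rate = prior$resid_scale),
                            n_draws, k))
  phi <- (s0 / 2) / stats::rgamma(n_draws, shape = nu0 / 2)
  num <- lam_sum^2 * phi
  num / (num + psi_sum)
}
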