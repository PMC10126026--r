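#' Posterior sampling for the classical-test-theory path
#'
#' With a near-flat prior on the item means (marginalized) and an
#' inverse-Wishart prior on the covariance matrix, the posterior of Sigma
#' given n complete rows is inverse-Wishart with scale
#' `scale_multiplier * I + C` (C the centered cross-product matrix) and
#' `df + n - 1` degrees of freedom. Draws are i.i.d. (conjugacy), but the
#' chain / burn-in / thinning structure is honored anyway so convergence
#' diagnostics work identically for the CTT and factor paths. When
#' `missing_strategy = "bayes_impute"` and missing cells are present, the
#' sampler alternates covariance draws with conditional-normal imputation
#' (data augmentation), making burn-in meaningful.
#'
#' @param data an [item_data] object.
#' @param prior a [ctt_prior].
#' @param mcmc an [mcmc_config].
#' @param seed integer seed.
#' @param missing_strategy `"listwise"` or `"bayes_impute"`.
#' @return list of class `cov_draws`: `draws` is a `k x k x kept x chains`
#'   array, plus `k`, `item_names`, `mcmc`.
#' @export
posterior_cov_draws <- function(data, prior = ctt_prior(), mcmc = mcmc_config(),
                                seed = 1L,
                                missing_strategy = c("listwise", "bayes_impute")) {
  stopifnot(inherits(data, "item_data"))
  missing_strategy <- match.arg(missing_strategy)
  k <- data$k
  df0 <- if (is.null(prior$df)) k else prior$df
  if (df0 < k) stop("invalid prior: df must be at least k = ", k)

  has_missing <- any(!data$mask)
  if (missing_strategy == "listwise" || !has_missing) {
    x <- complete_rows(data)
    n <- nrow(x)
    if (n < 2L) stop("fewer than 2 complete rows after listwise deletion")
    if (n < k) warning("fewer complete rows than items (n < k); ",
                       "posterior is prior-dominated")
    C <- crossprod(scale(x, center = TRUE, scale = FALSE))
    scale_post <- prior$scale_multiplier * diag(k) + C
    df_post <- df0 + n - 1
    if (min(eigen(scale_post, symmetric = TRUE,
                  only.values = TRUE)$values) <= 0)
      stop("posterior scale matrix is not positive definite")
    set.seed(seed)
    total <- mcmc$kept * mcmc$chains
    draws <- rinvwishart(total, scale_post, df_post)
    dim(draws) <- c(k, k, mcmc$kept, mcmc$chains)
  } else {
    draws <- cov_draws_augmented(data, prior$scale_multiplier, df0, mcmc, seed)
  }
  structure(list(draws = draws, k = k, item_names = data$item_names,
                 mcmc = mcmc),
            class = "cov_draws")
}

# inverse-Wishart draws: Sigma^-1 ~ Wishart(scale^-1, df)
rinvwishart <- function(n, scale, df) {
  w <- stats::rWishart(n, df = df, Sigma = chol2inv(chol(scale)))
  for (i in seq_len(n)) w[, , i] <- chol2inv(chol(w[, , i]))
  w
}

# data augmentation: alternate (Sigma, mu) draws with conditional-normal
# imputation of missing cells
cov_draws_augmented <- function(data, scale_mult, df0, mcmc, seed) {
  set.seed(seed)
  k <- data$k
  keep_row <- rowSums(data$mask) > 0L
  if (any(!keep_row))
    warning(sum(!keep_row), " fully missing row(s) excluded")
  x <- data$values[keep_row, , drop = FALSE]
  mask <- data$mask[keep_row, , drop = FALSE]
  n <- nrow(x)
  col_means <- colMeans(x, na.rm = TRUE)
  miss_rows <- which(rowSums(!mask) > 0L)

  out <- array(NA_real_, c(k, k, mcmc$kept, mcmc$chains))
  for (ch in seq_len(mcmc$chains)) {
    xc <- x
    for (i in miss_rows) xc[i, !mask[i, ]] <- col_means[!mask[i, ]]
    kept_i <- 0L
    for (it in seq_len(mcmc$iterations)) {
      C <- crossprod(scale(xc, center = TRUE, scale = FALSE))
      sigma <- rinvwishart(1L, scale_mult * diag(k) + C, df0 + n - 1)[, , 1L]
      mu <- colMeans(xc) +
        drop(crossprod(chol(sigma / n), stats::rnorm(k)))
      for (i in miss_rows) {
        xc[i, ] <- impute_missing_step(xc[i, ], mask[i, ], sigma, mu)
      }
      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
        kept_i <- kept_i + 1L
        if (kept_i <= mcmc$kept) out[, , kept_i, ch] <- sigma
      }
    }
  }
  out
}

#' One conditional-normal imputation step
#'
#' Draws the missing cells of a single row from their multivariate-normal
#' distribution conditional on the observed cells and current `(mu, sigma)`.
#' This is the building block of the Bayesian-imputation samplers.
#'
#' @param row numeric k-vector (missing entries may hold anything).
#' @param observed logical k-vector, `TRUE` = observed.
#' @param sigma current k x k covariance matrix.
#' @param mu current mean k-vector.
#' @return the completed row.
#' @export
impute_missing_step <- function(row, observed, sigma, mu) {
  if (!any(observed)) stop("fully missing row cannot be imputed")
  if (all(observed)) return(row)
  m <- !observed
  s_oo <- sigma[observed, observed, drop = FALSE]
  s_mo <- sigma[m, observed, drop = FALSE]
  w <- s_mo %*% solve(s_oo)
  cond_mean <- mu[m] + drop(w %*% (row[observed] - mu[observed]))
  cond_cov <- sigma[m, m, drop = FALSE] - w %*% t(s_mo)
  cond_cov <- (cond_cov + t(cond_cov)) / 2
  ev <- eigen(cond_cov, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  row[m] <- cond_mean + drop(rt %*% stats::rnorm(sum(m)))
  row
}

#' Map covariance draws through the CTT coefficients
#'
#' @param cov_draws a `cov_draws` object from [posterior_cov_draws].
#' @param which subset of `c("alpha", "lambda2", "lambda6", "glb")`.
#' @return named list of `coef_chains` objects (chains x kept matrices).
#' @export
ctt_coefficient_chains <- function(cov_draws,
                                   which = c("alpha", "lambda2", "lambda6",
                                             "glb")) {
  stopifnot(inherits(cov_draws, "cov_draws"))
  which <- match.arg(which, several.ok = TRUE)
  d <- cov_draws$draws
  k <- cov_draws$k
  kept <- dim(d)[3]; chains <- dim(d)[4]
  flat <- d
  dim(flat) <- c(k, k, kept * chains)
  out <- lapply(which, function(coefficient) {
    vals <- switch(coefficient,
      alpha   = apply_ctt(flat, cronbach_alpha, coefficient),
      lambda2 = apply_ctt(flat, guttman_lambda2, coefficient),
      lambda6 = apply_ctt(flat, guttman_lambda6, coefficient),
      glb     = as.numeric(.glb_solve_many(flat))
    )
    coef_chains(coefficient, matrix(vals, nrow = chains, ncol = kept,
                                    byrow = TRUE))
  })
  names(out) <- which
  out
}

apply_ctt <- function(flat, f, coefficient) {
  vapply(seq_len(dim(flat)[3]), function(i) {
    tryCatch(f(flat[, , i]), error = function(e) {
      stop(sprintf("%s failed on draw %d: %s", coefficient, i,
                   conditionMessage(e)), call. = FALSE)
    })
  }, numeric(1))
}

# chains x kept draws for one coefficient, class coef_chains
coef_chains <- function(coefficient, draws, prior_draws = NULL) {
  structure(list(coefficient = coefficient, draws = draws,
                 prior_draws = prior_draws),
            class = "coef_chains")
}

#' @export
print.coef_chains <- function(x, ...) {
  cat(sprintf("coef_chains: %s, %d chain(s) x %d draws\n", x$coefficient,
              nrow(x$draws), ncol(x$draws)))
  invisible(x)
}

#' Draws of the CTT coefficients under the prior
#'
#' Samples Sigma from the prior inverse-Wishart
#' `IW(scale_multiplier * I, df)` and maps each draw through the requested
#' coefficients. Used for the prior interval probabilities; the prior does
#' not involve the data, only the number of items.
#'
#' @param k number of items.
#' @param prior a [ctt_prior].
#' @param n_draws number of prior draws (at least 1000 recommended).
#' @param seed integer seed.
#' @param which coefficient subset as in [ctt_coefficient_chains].
#' @return named list of numeric vectors of length `n_draws`.
#' @export
prior_coefficient_draws <- function(k, prior = ctt_prior(), n_draws = 10000L,
                                    seed = 1L,
                                    which = c("alpha", "lambda2", "lambda6",
                                              "glb")) {
  which <- match.arg(which, several.ok = TRUE)
  df0 <- if (is.null(prior$df)) k else prior$df
  if (df0 < k) stop("invalid prior: df must be at least k = ", k)
  set.seed(seed)
  flat <- rinvwishart(n_draws, prior$scale_multiplier * diag(k), df0)
  out <- lapply(which, function(coefficient) {
    switch(coefficient,
      alpha   = apply_ctt(flat, cronbach_alpha, coefficient),
      lambda2 = apply_ctt(flat, guttman_lambda2, coefficient),
      lambda6 = apply_ctt(flat, guttman_lambda6, coefficient),
      glb     = as.numeric(.glb_solve_many(flat))
    )
  })
  names(out) <- which
  out
}
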