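pooled_factor_params <- function(draws) {
  ch <- dim(draws$loadings)[1]; kept <- dim(draws$loadings)[2]
  k <- draws$k
  lam <- matrix(aperm(draws$loadings, c(2, 1, 3)), ch * kept, k)
  psi <- matrix(aperm(draws$resid_var, c(2, 1, 3)), ch * kept, k)
  phi <- as.numeric(t(draws$latent_var))
  list(lam = lam, psi = psi, phi = phi, total = ch * kept)
}

#' Posterior predictive check on covariance eigenvalues
#'
#' For each of `n_reps` posterior draws, an n-row dataset is simulated from
#' the model-implied covariance `Sigma(theta)` and the (descending)
#' eigenvalues of its sample covariance are computed. The rank-wise 2.5% and
#' 97.5% quantiles form a 95% band; the observed eigenvalues of the data
#' covariance matrix should fall inside the bands when the unidimensional
#' model fits.
#'
#' @param data an [item_data] object (listwise-complete rows are used).
#' @param factor_draws a `factor_draws` object from [gibbs_factor_sampler].
#' @param n_reps number of predictive replications (default
#'   `min(1000, draws available)`).
#' @param seed integer seed.
#' @return object of class `ppc_result`: `observed`, `band_lower`,
#'   `band_upper` (k-vectors), `inside` (k logicals), `n_reps`.
#' @export
ppc_eigenvalues <- function(data, factor_draws, n_reps = NULL, seed = 1L) {
  stopifnot(inherits(data, "item_data"),
            inherits(factor_draws, "factor_draws"))
  S <- sample_covariance(data)
  n <- nrow(complete_rows(data))
  k <- ncol(S)
  par <- pooled_factor_params(factor_draws)
  if (is.null(n_reps)) n_reps <- min(1000L, par$total)
  if (n_reps > par$total) stop("n_reps exceeds available posterior draws")

  set.seed(seed)
  idx <- if (n_reps == par$total) seq_len(par$total)
         else sample.int(par$total, n_reps)
  sim_eig <- matrix(NA_real_, n_reps, k)
  for (r in seq_len(n_reps)) {
    j <- idx[r]
    sig <- implied_covariance(par$lam[j, ], par$psi[j, ], par$phi[j])
    x <- matrix(stats::rnorm(n * k), n, k) %*% chol(sig)
    sim_eig[r, ] <- sort(eigen(stats::cov(x), symmetric = TRUE,
                               only.values = TRUE)$values, decreasing = TRUE)
  }
  observed <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                   decreasing = TRUE)
  band_lower <- apply(sim_eig, 2, stats::quantile, probs = 0.025)
  band_upper <- apply(sim_eig, 2, stats::quantile, probs = 0.975)
  structure(list(observed = observed, band_lower = band_lower,
                 band_upper = band_upper,
                 inside = observed >= band_lower & observed <= band_upper,
                 n_reps = n_reps),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  df <- data.frame(rank = seq_along(x$observed), observed = x$observed,
                   lower = x$band_lower, upper = x$band_upper,
                   inside = x$inside)
  cat(sprintf("posterior predictive check (%d replications)\n", x$n_reps))
  print(df, row.names = FALSE)
  invisible(x)
}

ml_discrepancy <- function(S, sigma, logdetS, k) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdet <- 2 * sum(log(diag(ch)))
  logdet + sum(diag(S %*% chol2inv(ch))) - logdetS - k
}

#' Bayesian fit measures for the single-factor model
#'
#' Per posterior draw j, the likelihood-ratio discrepancy is
#' `chi2_j = (n - 1) * (log|Sigma_j| + tr(S Sigma_j^-1) - log|S| - k)` with S
#' the listwise-complete sample covariance. The effective number of
#' parameters pD is the DIC-style estimate `mean(chi2_j) - chi2(mean Sigma)`,
#' giving effective degrees of freedom `df* = k(k+1)/2 - pD`. Draw-wise
#' indices follow the classical formulas with df replaced by df*:
#' `BRMSEA_j = sqrt(max(chi2_j - df*, 0) / (df* (n - 1)))`, BCFI and BTLI
#' compare against an independence (diagonal-covariance) null model whose
#' posterior is sampled alongside. BLR is the posterior mean of `chi2_j`.
#'
#' @param data an [item_data] object.
#' @param factor_draws a `factor_draws` object.
#' @param thresholds named vector with elements `brmsea`, `bcfi`, `btli`
#'   giving the tail-probability cutoffs (defaults .08, .90, .90).
#' @param seed seed for the null-model variance draws.
#' @return object of class `fit_result`: per-index posterior mean and tail
#'   probability (`p(BRMSEA < .08)`, `p(BCFI > .90)`, `p(BTLI > .90)`),
#'   `blr`, `pd`, `df_eff`, draw vectors, and `n_skipped` singular draws.
#' @export
bayesian_fit_measures <- function(data, factor_draws,
                                  thresholds = c(brmsea = 0.08, bcfi = 0.90,
                                                 btli = 0.90),
                                  seed = 1L) {
  stopifnot(inherits(data, "item_data"),
            inherits(factor_draws, "factor_draws"))
  x <- complete_rows(data)
  n <- nrow(x)
  S <- stats::cov(x)
  k <- ncol(S)
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]
  par <- pooled_factor_params(factor_draws)
  total <- par$total

  chi2 <- numeric(total)
  sigma_sum <- matrix(0, k, k)
  for (j in seq_len(total)) {
    sig <- implied_covariance(par$lam[j, ], par$psi[j, ], par$phi[j])
    chi2[j] <- (n - 1) * ml_discrepancy(S, sig, logdetS, k)
    if (is.finite(chi2[j])) sigma_sum <- sigma_sum + sig
  }
  keep <- is.finite(chi2)
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    warning(n_skipped, " draw(s) skipped (singular implied covariance)")
  chi2 <- chi2[keep]
  sigma_bar <- sigma_sum / sum(keep)
  chi2_bar_model <- (n - 1) * ml_discrepancy(S, sigma_bar, logdetS, k)
  pd <- mean(chi2) - chi2_bar_model
  p_star <- k * (k + 1) / 2
  df_eff <- p_star - pd
  if (df_eff <= 0) {
    warning("effective degrees of freedom <= 0; fit indices unreliable")
    df_eff <- .Machine$double.eps
  }

  # independence (diagonal) null model: sigma_jj ~ IG((n-1)/2, C_jj/2)
  set.seed(seed)
  Cdiag <- diag(S) * (n - 1)
  m <- length(chi2)
  var_draws <- matrix(NA_real_, m, k)
  for (j in seq_len(k)) {
    var_draws[, j] <- (Cdiag[j] / 2) / stats::rgamma(m, shape = (n - 1) / 2)
  }
  chi2_null <- vapply(seq_len(m), function(i) {
    (n - 1) * ml_discrepancy(S, diag(var_draws[i, ], nrow = k), logdetS, k)
  }, numeric(1))
  null_bar <- diag(colMeans(var_draws), nrow = k)
  pd_null <- mean(chi2_null) - (n - 1) * ml_discrepancy(S, null_bar,
                                                        logdetS, k)
  df_null <- p_star - pd_null
  if (df_null <= 0) df_null <- .Machine$double.eps

  exc <- pmax(chi2 - df_eff, 0)
  exc_null <- pmax(chi2_null - df_null, 0)
  brmsea <- sqrt(exc / (df_eff * (n - 1)))
  bcfi <- 1 - exc / pmax(exc_null, exc, .Machine$double.eps)
  ratio_null <- chi2_null / df_null
  btli <- (ratio_null - chi2 / df_eff) / (ratio_null - 1)

  structure(list(
    brmsea = list(estimate = mean(brmsea),
                  p_below = mean(brmsea < thresholds[["brmsea"]]),
                  threshold = thresholds[["brmsea"]], draws = brmsea),
    bcfi = list(estimate = mean(bcfi),
                p_above = mean(bcfi > thresholds[["bcfi"]]),
                threshold = thresholds[["bcfi"]], draws = bcfi),
    btli = list(estimate = mean(btli),
                p_above = mean(btli > thresholds[["btli"]]),
                threshold = thresholds[["btli"]], draws = btli),
    blr = mean(chi2), pd = pd, df_eff = df_eff, n = n,
    n_skipped = n_skipped
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("BRMSEA = %.3f, p(BRMSEA < %.2f) = %.3f\n",
              x$brmsea$estimate, x$brmsea$threshold, x$brmsea$p_below))
  cat(sprintf("BCFI   = %.3f, p(BCFI > %.2f)   = %.3f\n",
              x$bcfi$estimate, x$bcfi$threshold, x$bcfi$p_above))
  cat(sprintf("BTLI   = %.3f, p(BTLI > %.2f)   = %.3f\n",
              x$btli$estimate, x$btli$threshold, x$btli$p_above))
  cat(sprintf("BLR    = %.2f (pD = %.2f, effective df = %.2f)\n",
              x$blr, x$pd, x$df_eff))
  invisible(x)
}
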