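#' Synthetic unidimensional item-response data
#'
#' Rows are drawn from the single-factor model `x = lambda * f + e` with
#' `f ~ N(0, latent_variance)` and `e ~ N(0, diag(residual_variances))`.
#' Exactly one of `loadings` and `target_omega` must be given; a target
#' omega is inverted into equal loadings `lambda = sqrt(w / (k (1 - w) + w))`
#' with residual variances `1 - lambda^2` (unit latent variance), so the
#' population omega matches the target exactly. Responses are continuous
#' (normal); `discretize = TRUE` rounds them onto a 0-4 Likert scale for
#' smoke tests shaped like real questionnaire data.
#'
#' @param n number of respondents.
#' @param k number of items.
#' @param loadings optional k-vector of loadings.
#' @param target_omega optional population omega in (0, 1).
#' @param residual_variances optional k-vector (> 0); derived when a target
#'   omega is given, default 1 - loading^2 otherwise.
#' @param latent_variance latent variance (default 1).
#' @param missing_rate MCAR missingness rate in \[0, 1); default 0.
#' @param discretize round to a 0-4 Likert scale (default FALSE).
#' @param seed integer seed.
#' @return an [item_data] object.
#' @export
make_unidimensional <- function(n, k, loadings = NULL, target_omega = NULL,
                                residual_variances = NULL,
                                latent_variance = 1, missing_rate = 0,
                                discretize = FALSE, seed = 1L) {
  if (is.null(loadings) == is.null(target_omega))
    stop("give exactly one of loadings and target_omega")
  if (!is.null(target_omega)) {
    if (target_omega <= 0 || target_omega >= 1)
      stop("target_omega must lie in (0, 1)")
    lam2 <- target_omega / (k * (1 - target_omega) + target_omega)
    loadings <- rep(sqrt(lam2), k)
    residual_variances <- rep(1 - lam2, k)
  } else {
    loadings <- rep_len(loadings, k)
    if (is.null(residual_variances))
      residual_variances <- 1 - latent_variance * loadings^2
  }
  if (any(residual_variances <= 0)) stop("residual variances must be > 0")
  set.seed(seed)
  f <- stats::rnorm(n, 0, sqrt(latent_variance))
  e <- matrix(stats::rnorm(n * k), n, k) *
    rep(sqrt(residual_variances), each = n)
  x <- tcrossprod(f, loadings) + e
  if (discretize) x <- pmin(pmax(round(x + 2), 0), 4)
  data <- item_data(x)
  if (missing_rate > 0) {
    data <- inject_missing(data, missing_rate, seed = seed + 1L)
  }
  attr(data, "generator") <- list(loadings = loadings,
                                  residual_variances = residual_variances,
                                  latent_variance = latent_variance)
  data
}

#' Multivariate-normal data from an arbitrary covariance matrix
#'
#' Zero-mean normal rows with population covariance `sigma`; rank-deficient
#' (psd) matrices are accepted via an eigenvalue square root.
#'
#' @param sigma symmetric psd covariance matrix.
#' @param n number of rows.
#' @param seed integer seed.
#' @return an [item_data] object.
#' @export
make_from_covariance <- function(sigma, n, seed = 1L) {
  sigma <- check_covariance(sigma)
  ev <- eigen(sigma, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  set.seed(seed)
  x <- matrix(stats::rnorm(n * ncol(sigma)), n) %*% rt
  item_data(x)
}

#' Two-factor (misfit) data for posterior-predictive checks
#'
#' Two blocks of items each loading on its own factor; the factors correlate
#' `between_corr`. Unless the correlation is near 1 the population
#' covariance has two dominant eigenvalues, so a unidimensional fit leaves
#' the second observed eigenvalue above its predictive band.
#'
#' @param n number of rows.
#' @param k_per_block items per block (total 2 * k_per_block).
#' @param between_corr factor correlation in \[0, 1).
#' @param loading common within-block loading (default `sqrt(0.5)`).
#' @param seed integer seed.
#' @return an [item_data] object.
#' @export
make_two_factor <- function(n, k_per_block, between_corr = 0,
                            loading = sqrt(0.5), seed = 1L) {
  if (between_corr < 0 || between_corr >= 1)
    stop("between_corr must lie in [0, 1)")
  k <- 2L * k_per_block
  set.seed(seed)
  phi <- matrix(c(1, between_corr, between_corr, 1), 2)
  fr <- matrix(stats::rnorm(2 * n), n) %*% chol(phi)
  lam <- matrix(0, k, 2)
  lam[seq_len(k_per_block), 1] <- loading
  lam[k_per_block + seq_len(k_per_block), 2] <- loading
  e <- matrix(stats::rnorm(n * k), n, k) * sqrt(1 - loading^2)
  item_data(fr %*% t(lam) + e)
}

#' Inject missing-completely-at-random cells
#'
#' Each cell is masked independently with probability `rate`; rows that
#' would end up fully missing are re-drawn, so no row is ever entirely
#' missing.
#'
#' @param data an [item_data] object.
#' @param rate missingness rate in \[0, 1).
#' @param mechanism only `"MCAR"` is implemented.
#' @param seed integer seed.
#' @return an [item_data] object with `NA`s injected.
#' @export
inject_missing <- function(data, rate, mechanism = "MCAR", seed = 1L) {
  stopifnot(inherits(data, "item_data"))
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(data)
  set.seed(seed)
  vals <- data$values
  for (i in seq_len(data$n)) {
    repeat {
      drop_cells <- stats::runif(data$k) < rate
      if (!all(drop_cells)) break
    }
    vals[i, drop_cells] <- NA_real_
  }
  item_data(vals, data$item_names)
}
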