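# toy covariance matrices with hand-derived coefficient values
toy2 <- matrix(c(1, .5, .5, 1), 2)                 # alpha=l2=glb=2/3, l6=.5
toy3 <- matrix(.5, 3, 3); diag(toy3) <- 1          # alpha=l2=glb=.75, l6=2/3

# n x k normal data whose sample covariance equals S exactly
data_with_exact_cov <- function(S, n, seed = 1L) {
  set.seed(seed)
  k <- ncol(S)
  x <- matrix(rnorm(n * k), n, k)
  xc <- scale(x, center = TRUE, scale = FALSE)
  x2 <- xc %*% solve(chol(cov(xc))) %*% chol(S)
  item_data(x2)
}

# constant factor_draws object (every draw at the same parameter values)
constant_factor_draws <- function(lambda, psi, phi, n, chains = 2L,
                                  kept = 25L) {
  k <- length(lambda)
  mc <- mcmc_config(chains = chains, iterations = kept, burn_in = 0L)
  loadings <- array(rep(lambda, each = chains * kept), c(chains, kept, k))
  resid_var <- array(rep(psi, each = chains * kept), c(chains, kept, k))
  latent_var <- matrix(phi, chains, kept)
  num <- sum(lambda)^2 * phi
  structure(list(loadings = loadings, resid_var = resid_var,
                 latent_var = latent_var,
                 omega = matrix(num / (num + sum(psi)), chains, kept),
                 k = k, n = n, item_names = paste0("item", seq_len(k)),
                 mcmc = mc, n_floored = 0L),
            class = "factor_draws")
}

# small default-shaped configs used across tests
quick_mcmc <- function(chains = 2L, iterations = 300L, burn_in = 50L) {
  mcmc_config(chains = chains, iterations = iterations, burn_in = burn_in)
}

random_psd <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(k * k), k)
  crossprod(a)
}
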