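#' Gelman-Rubin potential scale reduction (R-hat)
#'
#' Classic (non-split) formulation: with m chains of n draws, W the mean
#' within-chain variance and B the between-chain variance
#' (`n * var(chain means)`), `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`.
#' Values near 1 indicate mixing; above 1.1 is conventionally problematic
#' (see [rhat_flag]).
#'
#' @param chains numeric matrix, chains x draws, or a `coef_chains`.
#' @return scalar R-hat; `Inf` (with a warning) when W = 0 but B > 0.
#' @export
rhat <- function(chains) {
  if (inherits(chains, "coef_chains")) chains <- chains$draws
  chains <- as.matrix(chains)
  m <- nrow(chains); n <- ncol(chains)
  if (m < 2L) stop("rhat needs at least 2 chains")
  if (n < 2L) stop("rhat needs at least 2 draws per chain")
  W <- mean(apply(chains, 1, stats::var))
  B <- n * stats::var(rowMeans(chains))
  if (W == 0) {
    if (B > 0) {
      warning("zero within-chain variance with distinct chains; R-hat = Inf")
      return(Inf)
    }
    return(sqrt((n - 1) / n))   # all chains constant and equal
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence flag from R-hat
#'
#' @param r an R-hat value.
#' @param threshold flag cutoff (default 1.1).
#' @return `TRUE` when r exceeds the threshold (problematic), else `FALSE`.
#' @export
rhat_flag <- function(r, threshold = 1.1) {
  is.finite(r) && r > threshold || is.infinite(r)
}

#' Per-chain series for traceplots
#'
#' @param chains numeric matrix, chains x kept draws, or a `coef_chains`.
#' @return data frame with columns `chain`, `iteration`, `value` — kept
#'   iterations only, untransformed.
#' @export
traceplot_data <- function(chains) {
  if (inherits(chains, "coef_chains")) chains <- chains$draws
  chains <- as.matrix(chains)
  if (!length(chains)) stop("empty chains")
  data.frame(
    chain = rep(seq_len(nrow(chains)), each = ncol(chains)),
    iteration = rep(seq_len(ncol(chains)), times = nrow(chains)),
    value = as.numeric(t(chains))
  )
}
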