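pool_draws <- function(x) {
  if (inherits(x, "coef_chains")) as.numeric(t(x$draws)) else as.numeric(x)
}

#' Posterior point estimate
#'
#' Mean or median of the pooled (all chains) kept draws.
#'
#' @param draws numeric vector or `coef_chains`.
#' @param method `"mean"` or `"median"`.
#' @export
point_estimate <- function(draws, method = c("mean", "median")) {
  method <- match.arg(method)
  x <- pool_draws(draws)
  if (!length(x)) stop("empty chain")
  if (method == "mean") mean(x) else stats::median(x)
}

#' Highest-posterior-density interval
#'
#' Shortest interval containing `ceiling(mass * N)` of the sorted draws:
#' minimize `x[j + m - 1] - x[j]` over j, ties broken by the first (lowest)
#' window, so the result is deterministic given the draws.
#'
#' @param draws numeric vector or `coef_chains`.
#' @param mass probability mass in (0, 1]; default 0.95.
#' @return list of class `hpd_interval` with `lower`, `upper`, `mass`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass > 1) stop("mass must lie in (0, 1]")
  x <- sort(pool_draws(draws))
  n <- length(x)
  if (n < 100L) warning("fewer than 100 draws; HPD bounds will be noisy")
  m <- ceiling(mass * n)
  if (m >= n) {
    res <- c(x[1L], x[n])
  } else {
    width <- x[m:n] - x[1:(n - m + 1L)]
    j <- which.min(width)       # which.min takes the first minimum
    res <- c(x[j], x[j + m - 1L])
  }
  structure(list(lower = res[1L], upper = res[2L], mass = mass),
            class = "hpd_interval")
}

#' @export
print.hpd_interval <- function(x, ...) {
  cat(sprintf("%g%% HPD interval: [%.4f, %.4f]\n", 100 * x$mass,
              x$lower, x$upper))
  invisible(x)
}

#' Equal-tailed credible interval (central interval)
#'
#' @param draws numeric vector or `coef_chains`.
#' @param mass probability mass in (0, 1).
#' @export
central_interval <- function(draws, mass = 0.95) {
  x <- pool_draws(draws)
  a <- (1 - mass) / 2
  q <- stats::quantile(x, c(a, 1 - a), names = FALSE)
  structure(list(lower = q[1L], upper = q[2L], mass = mass),
            class = "hpd_interval")
}

#' Probability that draws fall strictly inside an interval
#'
#' @param draws numeric vector or `coef_chains`.
#' @param lo,hi interval cutoffs, `lo < hi`.
#' @export
prob_in_interval <- function(draws, lo, hi) {
  if (lo >= hi) stop("lo must be smaller than hi")
  x <- pool_draws(draws)
  mean(x > lo & x < hi)
}

# Gaussian kernel density of two samples on one shared 512-point grid
# (Silverman bandwidth per sample); used by the KL divergence and the
# posterior plots so both densities are comparable cell by cell.
shared_grid_density <- function(p, q, grid_size = 512L) {
  bw_p <- stats::bw.nrd0(p)
  bw_q <- stats::bw.nrd0(q)
  lo <- min(p, q) - 3 * max(bw_p, bw_q)
  hi <- max(p, q) + 3 * max(bw_p, bw_q)
  dp <- stats::density(p, bw = bw_p, from = lo, to = hi, n = grid_size)
  dq <- stats::density(q, bw = bw_q, from = lo, to = hi, n = grid_size)
  list(grid = dp$x, p = dp$y, q = dq$y)
}

#' Kullback-Leibler divergence between two sample sets
#'
#' KL(p || q) estimated on a shared 512-point kernel-density grid (Gaussian
#' kernel, Silverman's bandwidth), with the q density floored at 1e-12. The
#' divergence is asymmetric in its arguments.
#'
#' @param p_draws,q_draws numeric vectors (or `coef_chains`).
#' @param grid_size number of grid points (default 512).
#' @return nonnegative scalar.
#' @export
kl_divergence_samples <- function(p_draws, q_draws, grid_size = 512L) {
  p <- pool_draws(p_draws); q <- pool_draws(q_draws)
  if (!length(p) || !length(q)) stop("empty sample set")
  d <- shared_grid_density(p, q, grid_size)
  pp <- d$p / sum(d$p)
  qq <- pmax(d$q, 1e-12)
  qq <- qq / sum(qq)
  max(sum(pp * log(pp / qq), na.rm = TRUE), 0)
}

#' Kolmogorov-Smirnov distance between two sample sets
#'
#' Maximum absolute difference of the two empirical CDFs.
#'
#' @param p_draws,q_draws numeric vectors (or `coef_chains`).
#' @return scalar between 0 and 1.
#' @export
ks_distance_samples <- function(p_draws, q_draws) {
  p <- sort(pool_draws(p_draws)); q <- sort(pool_draws(q_draws))
  if (!length(p) || !length(q)) stop("empty sample set")
  pts <- sort(unique(c(p, q)))
  fp <- findInterval(pts, p) / length(p)
  fq <- findInterval(pts, q) / length(q)
  max(abs(fp - fq))
}

#' Kernel density estimate for plotting
#'
#' Gaussian kernel with Silverman's bandwidth h, evaluated on a grid
#' covering `[min - 3h, max + 3h]`; the trapezoid-rule integral is 1 up to
#' about 1e-3.
#'
#' @param draws numeric vector or `coef_chains`.
#' @param grid_size number of grid points (default 512).
#' @return data frame with columns `grid`, `density`.
#' @export
density_for_plot <- function(draws, grid_size = 512L) {
  x <- pool_draws(draws)
  if (!length(x)) stop("empty sample set")
  h <- stats::bw.nrd0(x)
  d <- stats::density(x, bw = h, from = min(x) - 3 * h, to = max(x) + 3 * h,
                      n = grid_size)
  data.frame(grid = d$x, density = d$y)
}
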