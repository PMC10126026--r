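CTT_COEFS <- c("alpha", "lambda2", "lambda6", "glb")

# one deterministic sub-seed per named random component, all below 2^31
derive_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 8L)
  names(s) <- c("ctt", "factor", "prior_ctt", "prior_omega", "ppc",
                "fit_null", "dropped", "spare")
  s
}

#' Run a full Bayesian reliability analysis
#'
#' Orchestrates the samplers and summaries: classical-test-theory
#' coefficients (alpha, lambda2, lambda6, glb) are mapped over
#' inverse-Wishart posterior draws of the covariance matrix, and McDonald's
#' omega over Gibbs draws of the unidimensional factor model. Output is a
#' summary table (point estimate, credible interval, R-hat) plus, on
#' request, interval probabilities, if-item-dropped tables, a posterior
#' predictive check, Bayesian fit measures and standardized loadings. The
#' run is deterministic given `config$seed`.
#'
#' @param data an [item_data] object.
#' @param config an [analysis_config].
#' @param ppc compute the posterior predictive eigenvalue check
#'   (omega must be requested).
#' @param fit_measures compute BRMSEA/BCFI/BTLI/BLR (omega must be
#'   requested).
#' @param std_loadings report standardized loadings (omega must be
#'   requested).
#' @param if_item_dropped `NULL`, or one of `"mean"`, `"kl"`, `"ks"`: rerun
#'   every coefficient on each k-1 item subset and order items by that
#'   divergence metric.
#' @return object of class `reliability_result`.
#' @export
run_analysis <- function(data, config = analysis_config(), ppc = FALSE,
                         fit_measures = FALSE, std_loadings = FALSE,
                         if_item_dropped = NULL) {
  stopifnot(inherits(data, "item_data"), inherits(config, "analysis_config"))
  wants_omega <- "omega" %in% config$coefficients
  if ((ppc || fit_measures || std_loadings) && !wants_omega)
    stop("ppc, fit_measures and std_loadings require the omega coefficient")
  if ("glb" %in% config$coefficients &&
      (nrow(complete_rows(data)) <= 1000 || data$k >= 10)) {
    warning("the glb has considerable positive bias except with more than ",
            "1000 observations and fewer than 10 items; interpret with care")
  }
  seeds <- derive_seeds(config$seed)

  chains <- collect_chains(data, config, seeds)

  factor_draws <- attr(chains, "factor_draws")
  interval_fun <- if (config$interval == "hpd") hpd_interval
                  else central_interval
  summary <- summarize_chains(chains, config, interval_fun)

  prob_table <- NULL
  if (!is.null(config$prob_interval)) {
    prob_table <- interval_probabilities(chains, config, seeds)
  }

  out <- list(summary = summary, chains = chains, prob_table = prob_table,
              config = config,
              n_complete = nrow(complete_rows(data)), k = data$k,
              item_names = data$item_names)
  if (ppc) {
    out$ppc <- ppc_eigenvalues(data, factor_draws, seed = seeds[["ppc"]])
  }
  if (fit_measures) {
    out$fit <- bayesian_fit_measures(data, factor_draws,
                                     seed = seeds[["fit_null"]])
  }
  if (std_loadings) {
    out$std_loadings <- standardized_loadings(factor_draws,
                                              config$point_estimate)
  }
  if (!is.null(if_item_dropped)) {
    out$item_dropped <- lapply(config$coefficients, function(coefficient) {
      item_dropped_analysis(data, config, coefficient,
                            metric = if_item_dropped,
                            full_chain = chains[[coefficient]])
    })
    names(out$item_dropped) <- config$coefficients
  }
  structure(out, class = "reliability_result")
}

# posterior chains for every requested coefficient; factor draws attached
collect_chains <- function(data, config, seeds) {
  chains <- list()
  factor_draws <- NULL
  ctt_wanted <- intersect(config$coefficients, CTT_COEFS)
  if (length(ctt_wanted)) {
    cov_draws <- posterior_cov_draws(data, config$ctt_prior, config$mcmc,
                                     seed = seeds[["ctt"]],
                                     missing_strategy = config$missing_strategy)
    chains <- ctt_coefficient_chains(cov_draws, ctt_wanted)
  }
  if ("omega" %in% config$coefficients) {
    factor_draws <- gibbs_factor_sampler(data, config$factor_prior,
                                         config$mcmc,
                                         seed = seeds[["factor"]],
                                         missing_strategy = config$missing_strategy)
    chains$omega <- omega_chain(factor_draws)
  }
  chains <- chains[intersect(config$coefficients, names(chains))]
  attr(chains, "factor_draws") <- factor_draws
  attr(chains, "k_items") <- data$k
  chains
}

summarize_chains <- function(chains, config, interval_fun) {
  rows <- lapply(chains, function(cc) {
    ci <- interval_fun(cc, config$ci_mass)
    data.frame(coefficient = cc$coefficient,
               estimate = point_estimate(cc, config$point_estimate),
               ci_lower = ci$lower, ci_upper = ci$upper,
               rhat = if (nrow(cc$draws) >= 2L) rhat(cc) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

interval_probabilities <- function(chains, config, seeds) {
  lo <- config$prob_interval[1]; hi <- config$prob_interval[2]
  ctt_wanted <- intersect(names(chains), CTT_COEFS)
  k_items <- attr(chains, "k_items")
  prior_ctt <- if (length(ctt_wanted)) {
    prior_coefficient_draws(
      k = k_items,
      prior = config$ctt_prior, n_draws = config$n_prior_draws,
      seed = seeds[["prior_ctt"]], which = ctt_wanted)
  } else list()
  rows <- lapply(names(chains), function(coefficient) {
    prior_draws <- if (coefficient == "omega") {
      prior_omega_draws(k = k_items,
                        prior = config$factor_prior,
                        n_draws = max(config$n_prior_draws, 10000L),
                        seed = seeds[["prior_omega"]])
    } else prior_ctt[[coefficient]]
    data.frame(coefficient = coefficient, lower = lo, upper = hi,
               prior_prob = prob_in_interval(prior_draws, lo, hi),
               posterior_prob = prob_in_interval(chains[[coefficient]],
                                                 lo, hi))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Bayesian reliability analysis: %d items, %d complete rows\n",
              x$k, x$n_complete))
  cat(sprintf("%d chain(s) x %d kept draws, %g%% %s intervals\n\n",
              x$config$mcmc$chains, x$config$mcmc$kept,
              100 * x$config$ci_mass, toupper(x$config$interval)))
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$prob_table)) {
    cat(sprintf("\nProbability that the coefficient lies in (%g, %g):\n",
                x$config$prob_interval[1], x$config$prob_interval[2]))
    print(x$prob_table, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$std_loadings)) {
    cat("\nStandardized loadings:\n")
    print(round(x$std_loadings, 4))
  }
  if (!is.null(x$ppc)) { cat("\n"); print(x$ppc) }
  if (!is.null(x$fit)) { cat("\n"); print(x$fit) }
  if (!is.null(x$item_dropped)) {
    for (coefficient in names(x$item_dropped)) {
      cat("\n"); print(x$item_dropped[[coefficient]])
    }
  }
  invisible(x)
}
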