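config_echo <- function(config) {
  fp <- config$factor_prior
  list(
    coefficients = config$coefficients,
    ci_mass = config$ci_mass,
    interval = config$interval,
    prob_interval = config$prob_interval,
    missing_strategy = config$missing_strategy,
    point_estimate = config$point_estimate,
    n_prior_draws = config$n_prior_draws,
    seed = config$seed,
    mcmc = unclass(config$mcmc),
    ctt_prior = unclass(config$ctt_prior),
    factor_prior = unclass(fp)
  )
}

#' Write an analysis report to disk
#'
#' `format = "json"` writes one self-contained file that echoes the full
#' configuration (priors, MCMC settings, seed) for provenance — MCMC results
#' vary slightly when rerun, and the echo makes that variation auditable.
#' `format = "csv"` treats `path` as a file prefix and writes one CSV per
#' table (`<path>_summary.csv`, plus `_probabilities`, `_item_dropped_*`,
#' `_ppc`, `_loadings` when present).
#'
#' @param results a `reliability_result` from [run_analysis].
#' @param path output file (json) or file prefix (csv).
#' @param format `"json"` or `"csv"`.
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, path, format = c("json", "csv")) {
  stopifnot(inherits(results, "reliability_result"))
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      config = config_echo(results$config),
      data = list(n_complete = results$n_complete, k = results$k,
                  item_names = results$item_names),
      summary = results$summary
    )
    if (!is.null(results$prob_table))
      payload$interval_probabilities <- results$prob_table
    if (!is.null(results$std_loadings))
      payload$standardized_loadings <- as.list(results$std_loadings)
    if (!is.null(results$ppc))
      payload$ppc <- results$ppc[c("observed", "band_lower", "band_upper",
                                   "inside", "n_reps")]
    if (!is.null(results$fit)) {
      f <- results$fit
      payload$fit <- list(
        brmsea = f$brmsea[c("estimate", "p_below", "threshold")],
        bcfi = f$bcfi[c("estimate", "p_above", "threshold")],
        btli = f$btli[c("estimate", "p_above", "threshold")],
        blr = f$blr, pd = f$pd, df_eff = f$df_eff)
    }
    if (!is.null(results$item_dropped)) {
      payload$item_dropped <- lapply(results$item_dropped, function(r) {
        list(coefficient = r$coefficient, metric = r$metric,
             full_mean = r$full_mean, table = r$table)
      })
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(path))
  }
  written <- character()
  w <- function(df, suffix) {
    p <- paste0(path, "_", suffix, ".csv")
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  w(results$summary, "summary")
  if (!is.null(results$prob_table)) w(results$prob_table, "probabilities")
  if (!is.null(results$std_loadings))
    w(data.frame(item = names(results$std_loadings),
                 loading = unname(results$std_loadings)), "loadings")
  if (!is.null(results$ppc))
    w(with(results$ppc,
           data.frame(rank = seq_along(observed), observed = observed,
                      lower = band_lower, upper = band_upper,
                      inside = inside)), "ppc")
  if (!is.null(results$item_dropped)) {
    for (coefficient in names(results$item_dropped))
      w(results$item_dropped[[coefficient]]$table,
        paste0("item_dropped_", coefficient))
  }
  invisible(written)
}

#' Export coefficient chains to a long-format CSV
#'
#' Columns: `draw`, `chain`, `coefficient`, `value`.
#'
#' @param chains a `coef_chains` or a list of them.
#' @param path output CSV path.
#' @export
write_chains_csv <- function(chains, path) {
  if (inherits(chains, "coef_chains")) chains <- list(chains)
  rows <- lapply(chains, function(cc) {
    td <- traceplot_data(cc)
    data.frame(draw = td$iteration, chain = td$chain,
               coefficient = cc$coefficient, value = td$value)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
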