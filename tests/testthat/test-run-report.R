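test_that("minimal request yields exactly one coefficient row", {
  d <- data_with_exact_cov(toy2, 60, seed = 81)
  cfg <- analysis_config(coefficients = "alpha", mcmc = quick_mcmc(),
                         seed = 3)
  res <- run_analysis(d, cfg)
  expect_equal(nrow(res$summary), 1L)
  expect_equal(res$summary$coefficient, "alpha")
  expect_true(res$summary$ci_lower <= res$summary$ci_upper)
})

test_that("runs are bit-identical under a fixed seed", {
  d <- make_unidimensional(n = 80, k = 4, target_omega = .75, seed = 82)
  cfg <- analysis_config(coefficients = c("omega", "alpha", "glb"),
                         prob_interval = c(.7, .9), mcmc = quick_mcmc(),
                         n_prior_draws = 500, seed = 11)
  expect_warning(r1 <- run_analysis(d, cfg), "positive bias")  # glb, n small
  r2 <- suppressWarnings(run_analysis(d, cfg))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$prob_table, r2$prob_table)
})

test_that("listwise and imputation agree end-to-end on complete data", {
  d <- make_unidimensional(n = 70, k = 4, target_omega = .75, seed = 83)
  base <- analysis_config(coefficients = c("omega", "alpha"),
                          mcmc = quick_mcmc(), seed = 21)
  imp <- analysis_config(coefficients = c("omega", "alpha"),
                         missing_strategy = "bayes_impute",
                         mcmc = quick_mcmc(), seed = 21)
  expect_identical(run_analysis(d, base)$summary,
                   run_analysis(d, imp)$summary)
})

test_that("omega-only outputs are refused when omega is not requested", {
  d <- data_with_exact_cov(toy3, 50, seed = 84)
  cfg <- analysis_config(coefficients = "alpha", mcmc = quick_mcmc())
  expect_error(run_analysis(d, cfg, ppc = TRUE), "omega")
  expect_error(run_analysis(d, cfg, fit_measures = TRUE), "omega")
  expect_error(run_analysis(d, cfg, std_loadings = TRUE), "omega")
})

test_that("JSON report round-trips and echoes the configuration", {
  d <- make_unidimensional(n = 60, k = 4, target_omega = .75, seed = 85)
  cfg <- analysis_config(coefficients = c("omega", "alpha"),
                         prob_interval = c(.7, .9), mcmc = quick_mcmc(),
                         n_prior_draws = 500, seed = 13)
  res <- run_analysis(d, cfg, std_loadings = TRUE)
  path <- tempfile(fileext = ".json")
  write_report(res, path, "json")
  back <- jsonlite::read_json(path, simplifyVector = TRUE)

  expect_equal(back$summary$estimate, res$summary$estimate,
               tolerance = 1e-6)
  expect_equal(back$summary$ci_lower, res$summary$ci_lower,
               tolerance = 1e-6)
  expect_equal(back$interval_probabilities$prior_prob,
               res$prob_table$prior_prob, tolerance = 1e-6)
  expect_equal(back$interval_probabilities$posterior_prob,
               res$prob_table$posterior_prob, tolerance = 1e-6)
  # provenance echo: priors, MCMC settings, seed
  expect_equal(back$config$seed, 13)
  expect_equal(back$config$mcmc$iterations, 300)
  expect_equal(back$config$ctt_prior$scale_multiplier, 1e-10)
  expect_equal(back$config$factor_prior$resid_shape, 2)
})

test_that("CSV report writes one file per table", {
  d <- make_unidimensional(n = 60, k = 4, target_omega = .75, seed = 86)
  cfg <- analysis_config(coefficients = "alpha",
                         prob_interval = c(.7, .9), mcmc = quick_mcmc(),
                         n_prior_draws = 300, seed = 14)
  res <- run_analysis(d, cfg)
  prefix <- file.path(tempdir(), "report")
  files <- write_report(res, prefix, "csv")
  expect_true(all(file.exists(files)))
  summ <- read.csv(paste0(prefix, "_summary.csv"))
  expect_equal(summ$estimate, res$summary$estimate, tolerance = 1e-6)
  expect_true(file.exists(paste0(prefix, "_probabilities.csv")))
})

test_that("chains export to long CSV", {
  cc <- structure(list(coefficient = "alpha",
                       draws = matrix(1:6 / 10, 2, 3)),
                  class = "coef_chains")
  path <- tempfile(fileext = ".csv")
  write_chains_csv(cc, path)
  back <- read.csv(path)
  expect_equal(names(back), c("draw", "chain", "coefficient", "value"))
  expect_equal(nrow(back), 6L)
})

test_that("command-line interface: simulate, coef, run", {
  tmp <- tempdir()
  sim <- file.path(tmp, "cli_sim.csv")
  expect_equal(relicred_main(c("simulate", "--n", "60", "--k", "4",
                               "--omega", "0.8", "--seed", "3",
                               "--out", sim)), 0L)
  expect_true(file.exists(sim))

  sig <- file.path(tmp, "cli_sigma.csv")
  write.csv(as.data.frame(toy3), sig, row.names = FALSE)
  out <- capture.output(status <- relicred_main(
    c("coef", sig, "--coefficient", "glb")))
  expect_equal(status, 0L)
  expect_match(paste(out, collapse = "\n"), "0.75")

  rep_prefix <- file.path(tmp, "cli_report")
  out2 <- capture.output(status2 <- relicred_main(
    c("run", sim, "--coefficients", "alpha", "--chains", "2",
      "--iter", "200", "--burnin", "20", "--seed", "5",
      "--out", rep_prefix, "--format", "json")))
  expect_equal(status2, 0L)
  expect_true(file.exists(paste0(rep_prefix, ".json")))

  expect_equal(suppressMessages(relicred_main(c("run"))), 1L)
  expect_equal(relicred_main(character()), 1L)
})
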