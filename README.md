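# relicred — Bayesian single-test reliability analysis

Most questionnaire studies report a single point estimate of Cronbach's α
and nothing about its uncertainty, even though a reliability coefficient is
itself estimated from noisy data. `relicred` is a scriptable R library and
command-line tool that produces full posterior distributions — and hence
credible intervals and interval probabilities — for five single-test
reliability coefficients:

- **McDonald's ω** — reliability under the unidimensional factor model
  `x = λf + e`, `f ~ N(0, φ)`, `e ~ N(0, diag(ψ))`:
  `ω = (Σλ_i)² φ / ((Σλ_i)² φ + Σψ_i)`
- **Cronbach's α** — `α = k/(k−1) · (1 − tr Σ / 1'Σ1)`
- **Guttman's λ₂** — `λ₂ = [1'Σ1 − tr Σ + √(k/(k−1) · Σ_{i≠j} σ_ij²)] / 1'Σ1`
- **Guttman's λ₆** — `1 − Σ_i ψ̂_i / 1'Σ1`, with `ψ̂_i = 1/[Σ⁻¹]_ii` the
  residual variance of item i regressed on the rest
- **greatest lower bound (glb)** — `1 − max Σθ_i / 1'Σ1` subject to
  `Σ − diag(θ)` positive semidefinite and `0 ≤ θ_i ≤ σ_ii`, solved as a
  small semidefinite program by an interior-point method

The classical-test-theory coefficients (α, λ₂, λ₆, glb) are given a
posterior by conjugate inverse-Wishart sampling of the item covariance
matrix; ω by a Gibbs sampler for the single-factor model. On top of the
samplers the package provides HPD credible intervals, prior/posterior
probabilities for user-defined intervals, if-item-dropped analysis (with
mean-difference, Kullback-Leibler, and Kolmogorov-Smirnov orderings and
item-rest correlations), Gelman-Rubin R-hat and traceplot data, a
posterior-predictive check on covariance eigenvalues, Bayesian fit measures
(BRMSEA, BCFI, BTLI, BLR), Bayesian imputation of missing responses, and
deterministic synthetic-data generators.

## Worked example

```r
library(relicred)

# synthetic 0-4 Likert data shaped like a small questionnaire study:
# 78 respondents, 5 items, population omega .8
d <- make_unidimensional(n = 78, k = 5, target_omega = .8, seed = 42,
                         discretize = TRUE)

cfg <- analysis_config(coefficients = c("omega", "alpha"),
                       prob_interval = c(.70, .90), seed = 1)
res <- run_analysis(d, cfg, ppc = TRUE)
print(res)
```

```
Bayesian reliability analysis: 5 items, 78 complete rows
3 chain(s) x 950 kept draws, 95% HPD intervals

 coefficient estimate ci_lower ci_upper   rhat
       omega   0.8009   0.7309   0.8670 0.9997
       alpha   0.8062   0.7430   0.8765 1.0003

Probability that the coefficient lies in (0.7, 0.9):
 coefficient lower upper prior_prob posterior_prob
       omega   0.7   0.9     0.1305         0.9951
       alpha   0.7   0.9     0.0915         0.9926

posterior predictive check (1000 replications)
 rank  observed     lower     upper inside
    1 2.9636330 1.8826137 4.6363062   TRUE
    2 0.8105361 0.5879136 1.0858394   TRUE
    3 0.6117816 0.4623570 0.8015198   TRUE
    4 0.4092906 0.3555303 0.6347438   TRUE
    5 0.3870765 0.2403436 0.4740557   TRUE
```

Reading the output: the posterior mean of ω is .80 and, with 95%
probability, ω lies in [.73, .87]; R-hat ≈ 1 says the three chains mixed.
The data moved the probability that ω falls in the band (.70, .90) from a
prior 13% to over 99%. All five observed covariance eigenvalues sit inside
their 95% posterior-predictive bands, so the unidimensional model (and
hence ω) is tenable for these data. `write_report(res, "out.json")` saves
everything, including a full echo of priors, MCMC settings, and seed.

## Command line

```sh
# simulate -> analyze -> machine-readable report
Rscript inst/cli/relicred simulate --n 78 --k 5 --omega .8 --seed 1 --out sim.csv
Rscript inst/cli/relicred run sim.csv --coefficients omega alpha glb \
    --prob-interval 0.70 0.90 --ppc --seed 7 --out report --format json

# desk-check a coefficient on a covariance matrix stored as CSV
Rscript inst/cli/relicred coef SIGMA.csv --coefficient glb
```

(After installation the same script is available at
`system.file("cli", "relicred", package = "relicred")`.)

## Defaults

3 chains × 1000 iterations, burn-in 50, thinning 1; 95% HPD intervals;
inverse-Wishart(10⁻¹⁰·I, k) prior on Σ; inverse-gamma(2, 1) priors on
residual variances, N(0, 1) on loadings, scalar inverse-Wishart(k, k+2) on
the latent variance. See `vignettes/bayesian-reliability.Rmd` for why.
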