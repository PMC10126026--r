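---
title: "Bayesian single-test reliability: models, priors, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian single-test reliability: models, priors, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`relicred` estimates the uncertainty of single-test reliability
coefficients by giving each of them a posterior distribution. This
vignette documents the two sampling models, every tunable prior with its
default and rationale, the numerical choices that are not forced by the
statistics, what the synthetic-data generators do and do not emulate, and
the known limitations.

## Two routes to a posterior

**Classical-test-theory route (α, λ₂, λ₆, glb).** Each of these
coefficients is a deterministic function of the item covariance matrix Σ.
With multivariate-normal responses, a (near-flat) flat prior on the item
means — which are then marginalized out — and an inverse-Wishart prior
`Σ ~ IW(s·I, ν)`, the posterior is again inverse-Wishart:

    Σ | X  ~  IW(s·I + C,  ν + n − 1),

where `C` is the centered cross-product matrix of the n complete rows.
Posterior draws of each coefficient are simply the coefficient evaluated
at i.i.d. draws of Σ. Because the update is conjugate there is no true
Markov chain; the chain/burn-in/thinning interface is honored anyway so
that R-hat and traceplots behave identically on both routes. (Whether the
posterior degrees of freedom use n or n − 1 is a convention; this package
uses `ν + n − 1`, consistent with the marginalized mean. At realistic n
the difference is invisible.)

**Factor route (ω).** ω is defined through the unidimensional factor
model `x_i = λ f_i + e_i`, `f_i ~ N(0, φ)`, `e_i ~ N(0, diag(ψ))`:

    ω = (Σ λ_j)² φ / ((Σ λ_j)² φ + Σ ψ_j).

The posterior is simulated by a Gibbs sampler with the latent scores
sampled explicitly (data augmentation) and full conditionals cycled in a
fixed order: scores → loadings → residual variances → latent variance.
All conditionals are standard normal-linear/inverse-gamma updates. Data
are column-centered first; intercepts are not modeled because reliability
depends only on the covariance structure.

The factor model is identified only up to a sign flip of (λ, f). ω is
invariant, but loading tables are not, so after every iteration the
sampler reflects the draw (`λ → −λ`, `f → −f`) whenever `Σλ < 0`. This
keeps the loading-sum chain single-moded and makes reported loadings
reproducible. Reported loadings are standardized,
`λ_j √φ / √(φ λ_j² + ψ_j)`, which is invariant to the (unidentified)
scale split between φ and λ.

## Priors, defaults, and the one undocumented constant

| parameter | prior | default | notes |
|---|---|---|---|
| Σ (CTT route) | inverse-Wishart(s·I, ν) | s = 10⁻¹⁰, ν = k | s acts as a precision; the tiny default makes the prior near-flat while keeping the posterior proper. ν must be ≥ k. |
| ψ_j (residual variances) | inverse-gamma(shape, scale) | (2, 1) | prior mean 1, matching unit-variance items. |
| λ_j (loadings) | normal(m, s) | (0, 1) | see below. |
| φ (latent variance) | scalar inverse-Wishart(scale, df) ≡ inverse-gamma(df/2, scale/2) | (k, k + 2) | a 1×1 inverse-Wishart is an inverse-gamma; implemented as such. |
| MCMC | — | 3 chains × 1000 iterations, burn-in 50, thin 1 | conjugate updates mix essentially instantly; the defaults are generous. |

The loading-prior *standard deviation* is the one constant the reference
specification leaves open (only the mean is exposed there). It matters: it
controls how much prior mass ω places on high values. The default of 1 was
validated by simulation: with k = 5 and all other defaults, 200,000 prior
draws give P(.70 < ω < .90) = 0.133 ± 0.001, matching the published
reference value of .132 for this configuration. Halving the SD drops that
mass to ~.06; doubling it raises it to ~.27. The value is exposed as
`factor_prior(loading_sd = )` and echoed in every report.

The induced prior on ω is far from uniform: it concentrates mass at low
values and places little near 1 (P(ω > .95) < .05 at the defaults), which
is worth knowing before interpreting posterior interval probabilities.

## Numerical choices

**glb.** The greatest lower bound is the optimum of a semidefinite
program: maximize Σθ_i subject to `Σ − diag(θ)` psd and
`0 ≤ θ_i ≤ σ_ii`. Because θ has only k entries, the package solves it
with a primal log-barrier interior-point method (compiled, RcppArmadillo):
exact damped Newton steps on θ, barrier parameter driven down a geometric
path, final suboptimality certified below `tol` (default 10⁻⁸; Newton-step
cap 10,000). Σ is rescaled to unit mean diagonal first — every coefficient
here is invariant under `Σ → c²Σ` — so the tolerance is scale-free. An
ADMM splitting scheme was tried first and abandoned: on near-singular
draws (where glb → 1) its residuals stall around 10⁻⁴. The interior-point
solver shows zero ordering violations (α ≤ λ₂ ≤ glb) on 1000 random psd
matrices and matches brute-force grid search at k = 2. Exactly singular
input is ridged by 10⁻¹² · max σ_ii, far below the reporting precision.

**λ₆ and singular matrices.** λ₆ needs Σ⁻¹. The package refuses singular
input instead of ridging it silently: regularization changes the estimand,
and a singular sample covariance is a property of the data the analyst
should see.

**HPD intervals** use the sorted-window method: among all windows of
`⌈mass·N⌉` consecutive sorted draws, the shortest one wins, ties going to
the lowest window — deterministic given the draws. HPD is used for all
coefficients uniformly (the reference output mixes wording); an
equal-tailed alternative is available via `analysis_config(interval =
"central")`.

**KL and KS distances** (if-item-dropped orderings) are estimated from
pooled draws: KS as the exact maximum ECDF gap; KL on a shared 512-point
grid covering both samples (Gaussian kernel, Silverman's bandwidth per
sample, q floored at 10⁻¹²). The KL estimator is accurate when p is no
wider than q (e.g., N(0,1) vs N(1,1) reproduces 0.5 within .05) but
inflates when p's tails extend far beyond q's, where the floor dominates;
for ordering posteriors of the same coefficient — the only use here —
the distributions are comparable and the bias is immaterial.

**Fit measures.** Per posterior draw j, the likelihood-ratio discrepancy
against the listwise sample covariance S is
`χ²_j = (n−1)·(ln|Σ_j| + tr(S Σ_j⁻¹) − ln|S| − k)`. The effective number
of parameters pD is the DIC-style (devM) estimate
`mean(χ²_j) − χ²(Σ̄)`, giving effective degrees of freedom
`df* = k(k+1)/2 − pD`. BRMSEA, BCFI and BTLI are the classical formulas
with df replaced by df*, the null being an independence model whose
diagonal-variance posterior is sampled alongside
(`σ_jj ~ IG((n−1)/2, C_jj/2)`). BLR is reported as the posterior mean of
χ²_j; the source naming it gives no formula, so this choice is documented
rather than asserted against a published value, and it behaves as required
(zero under perfect fit, growing with misfit). Fit measures always target
the listwise-complete S, even under imputation — a single observed
comparison matrix is needed; this is a documented limitation.

**Posterior-predictive check.** For each of `n_reps` (default ≤ 1000)
posterior draws, an n-row dataset is simulated from the implied
covariance `φλλᵀ + diag(ψ)` and the descending eigenvalues of its sample
covariance recorded; rank-wise 2.5%/97.5% quantiles (linear
interpolation) form the bands. Under a correctly specified model the
bands cover each observed eigenvalue with ≈95% probability; two-factor
data push the second eigenvalue above its band.

**Missing data.** `listwise` drops incomplete rows. `bayes_impute` treats
missing cells as parameters: on the CTT route the sampler alternates
Σ-draws, a mean draw, and conditional-normal imputation of each
incomplete row (so burn-in becomes meaningful); on the factor route
missing cells are redrawn from `N(λ_j f_i, ψ_j)` each iteration. Missing
cells start at item means — any proper starting point converges, and item
means are a neutral choice. Fully missing rows are excluded with a
warning. With no missing cells both strategies produce bit-identical
results at equal seeds.

**If-item-dropped** reruns the relevant sampler on every (k−1)-item
subset with the same MCMC settings and the same derived seed as the full
model, for comparability of the posteriors. Dropping from k = 2 is
refused (a single item has no internal consistency). For unidimensional
data, deleting an item typically widens the posterior — this is asserted
in the test suite as a mean effect over 20 simulated datasets, not
per run.

## What the generators emulate — and what a green test does not establish

`make_unidimensional()` draws continuous multivariate-normal responses
from a single-factor model; a target ω is inverted into equal loadings
`λ = √(ω / (k(1−ω) + ω))`, `ψ = 1 − λ²`, `φ = 1`, so the population ω
matches the target exactly. `make_from_covariance()` draws zero-mean
normal rows from any psd matrix; `make_two_factor()` builds two-block
misfit data; `inject_missing()` masks cells MCAR, re-drawing rows that
would become fully missing.

Real questionnaire data are bounded, discrete, often skewed, and their
missingness is rarely MCAR. The generators deliberately stay in the
normal world because both sampling models are normal-theory models — a
green parameter-recovery or calibration test therefore establishes that
the machinery is correct *under the model*, not that the model is
adequate for ordinal Likert data (a `discretize` option rounds onto a 0-4
scale for interface smoke tests only, without any claim about polychoric
behavior). Likewise, MCAR-based imputation tests do not validate
imputation under informative missingness.

## Scaled-down checks and external data

Two verification points deserve transparency. First, the acceptance test
that reproduces the published 78×5 worked example requires the original
OSF dataset, which is not redistributable with the package; without the
file that test reports its absence as a failure rather than silently
skipping. Second, the misfit-detection calibration (200 replications of a
fit-then-check cycle) runs each replication with a reduced sampler — one
chain, 350 iterations — purely for time budget; the conjugate-style
updates mix fast enough that this does not change the detection rate
materially, and the correctly-specified coverage check uses bands from
the true model with no reduction.

## Known limitations

- All coefficients assume continuous, roughly multivariate-normal
  responses; no polychoric/ordinal variants.
- Single-factor ω only: no bifactor, hierarchical, or multi-factor ω.
- The glb has considerable positive bias in small samples; the package
  warns (but does not refuse) when n ≤ 1000 or k ≥ 10.
- MCAR is the only missingness mechanism generated or tested.
- BLR follows this package's documented definition (posterior mean of the
  LR discrepancy); comparisons with other software should compare
  formulas first.
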