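---
title: "Spatio-temporal Bayesian modelling of Aedes trap counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal Bayesian modelling of Aedes trap counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Urban *Aedes aegypti* and *Aedes albopictus* surveillance programs count
adult mosquitoes in baited traps, one count per trap-night and species.
The counts are overdispersed, zero-heavy (especially for the rarer
species), unbalanced across sites and seasons, and spatially correlated at
sub-kilometre distances because adult *Aedes* rarely disperse more than
~1 km. `aedesmapr` implements a complete workflow for such data:
predictor screening, count-family selection, a spatial hierarchical fit,
posterior-predictive validation and gridded weekly prediction, with a
synthetic-data generator so every stage can be exercised and tested
without access to any surveillance database.

## The model

For trap-night $i$ at site $s_i$ the count model is

$$
y_i \sim \mathrm{NB}(\mu_i, n), \qquad
\log \mu_i = \beta_0 + x_i^\top \beta + u(s_i),
$$

with Poisson and zero-inflated Poisson (ZIP) available as alternative
families for the model-comparison step. Covariates $x_i$ are standardized
(mean 0, sd 1), so coefficients are log incidence-rate ratios per SD; lag-1
and lag-2 weather covariates are the daily values 7 and 14 days before the
observation, not weekly means. The site-level field $u$ is a zero-mean
Gaussian random field with Matérn covariance of smoothness $\nu = 1$ (the
standard 2-D choice),

$$
C(d) = \sigma^2 (\kappa d) K_1(\kappa d), \qquad \kappa = \sqrt{8}/\rho,
$$

so the *range* $\rho$ is the distance at which correlation has decayed to
about 0.1. The field is constant over the study year: it absorbs
unmeasured site-level structure (microhabitat, control effort), not
space–time interaction.

### Priors

Hyperparameters carry penalized-complexity (PC) priors, calibrated by
interpretable tail statements and shrinking toward the simpler base model:

* range: $\pi(\rho) = (\lambda_\rho/\rho^2) e^{-\lambda_\rho/\rho}$ with
  $\lambda_\rho = -\rho_0 \ln p_\rho$; the default calibration is
  $P(\rho < 10\,\mathrm{km}) = 0.95$ — dispersal makes correlation beyond
  half the study width implausible;
* field sd: $\pi(\sigma) = \lambda_\sigma e^{-\lambda_\sigma \sigma}$ with
  $\lambda_\sigma = -\ln(p_\sigma)/\sigma_0$ and default
  $P(\sigma > 0.5) = 0.05$ — the spatial effect should be small relative
  to the covariate effects;
* fixed effects: $\mathrm{N}(0, 10^2)$ on the standardized scale (weakly
  informative; the reference software's "default" covariate priors are
  idiosyncratic to it, so we declare our own);
* NB size: an exponential PC-style prior on $1/\sqrt{n}$, shrinking toward
  the Poisson limit, with rate set so $P(n < 1) = 0.05$;
* ZIP zero-inflation: Beta(1, 1).

Both PC calibrations hold exactly in closed form and are verified by
numerical integration in the test suite.

### Inference

Fitting is by adaptive Metropolis-within-Gibbs MCMC over the exact joint
posterior — with ~50 sites a dense-covariance formulation is cheap, so no
SPDE/Laplace approximation is needed; the model, not any particular
approximation algorithm, is what the package implements. The update cycle
is: per-coordinate and joint adaptive random walks on $\beta$ (the joint
proposal learns the posterior covariance during warmup), single-site random
walks on $u$ with the conditional Gaussian prior evaluated through the
precision matrix, a likelihood-invariant "swap" move that shifts mass
between the intercept and the field mean (these two are only weakly
identified), separate random walks on $\log\rho$ and $\log\sigma$ with the
Cholesky factor recomputed on proposal, and scalar walks on $\log n$ /
$\mathrm{logit}\,\pi_0$. All proposal scales adapt by Robbins–Monro during
warmup only, targeting 0.44 (scalar) or 0.25 (joint) acceptance. Chains
start from a jittered Poisson-GLM fit; at least two chains are required,
and the fit aborts (by default) if any monitored split-$\hat R$ exceeds
1.05. A $10^{-8}\sigma^2$ diagonal jitter keeps the Matérn factorization
stable.

Model choice uses $\mathrm{DIC} = \bar D + p_D$, $p_D = \bar D -
D(\bar\theta)$, with $\bar\theta$ the posterior mean of the linear
predictor and family parameters. Fit adequacy uses the Pearson
overdispersion statistic $\sum_i (y_i - \hat m_i)^2 / V(\hat m_i) / (N-p)$
computed per posterior draw ($p$ counts fixed effects only — a declared
choice, since conventions differ), and a posterior-predictive simulation
study: 1,000 datasets simulated from 1,000 posterior draws, count-histogram
bands at pointwise 2.5/97.5 percentiles, and Pearson-residual quantiles
compared against the simulated envelope. "Scaled residuals" are Pearson
residuals, consistent with the overdispersion statistic.

### Variable selection

Candidate predictors are screened with a normal-mixture-of-inverse-Gammas
style spike-and-slab: $\beta_j \mid \gamma_j \sim \mathrm{N}(0, \gamma_j
v_1 + (1-\gamma_j) v_0)$, $\gamma_j \sim \mathrm{Bernoulli}(w)$, defaults
$v_0 = 0.005^2$, $v_1 = 2.5^2$, $w = 0.5$ (weakly informative on
standardized covariates). The likelihood during selection is negative
binomial — the family the final models use — rather than a Gaussianized
response; smooth (spline) terms are not implemented because all finally
selected predictors enter linearly. The inclusion probability is the
posterior mean of $\gamma_j$ and the "scaled effect" the posterior mean of
$\beta_j$ (a posterior-median variant would be equally defensible; the
mean is declared, not inferred from the reference analysis). The final
rule keeps, per weather variable, only the lag with the largest
$|$effect$|$, shortlists the top 12 by inclusion probability, and returns
the six largest absolute effects, breaking ties alphabetically. The
Gaussian-likelihood variant of the sampler is validated in the tests
against brute-force enumeration of all $2^p$ inclusion configurations with
the coefficient vector integrated out analytically.

## The synthetic-data generator

The generator emulates the structure the model assumes, at the scale of a
one-year municipal program:

* 51 sites uniform in an 11.3-km square — that side length reproduces a
  mean inter-site distance of ~5.9 km (mean pairwise distance in a square
  is 0.5214 × side);
* unbalanced sampling, mean 100 observations per site with a floor of 30
  (mirroring the rule that discards sparser sites);
* covariates drawn i.i.d. standard normal: the model consumes standardized
  covariates, and no raw-scale summary statistics are available to emulate,
  so the generator works directly on that scale;
* one Matérn($\nu=1$) field draw per dataset, constant in time;
* daily weather as seasonal sinusoids plus AR(1) noise, with the
  temperature–humidity Spearman correlation tunable (default target 0.61)
  and humidity's seasonal phase a quarter-cycle later than temperature's;
* two reference scenarios whose generating coefficient vectors are the
  published abundant-species (*Ae. aegypti*-like, intercept 1.59) and
  rare-species (*Ae. albopictus*-like, intercept −1.50) estimates.

Constants the source estimates do not pin down were chosen once as
plausible field values and not revisited: field sd $\sigma = 0.3$ (the
prior calibration treats 0.5 as large) and NB size $n = 1$, which with the
scenario intercepts yields roughly one-in-five zero trap-nights for the
abundant species and three-in-four or more for the rare one — the
qualitative zero-inflation contrast of real *Aedes* programs. Exact
published zero fractions cannot be matched by any generator without the
real covariate distributions. What passing tests show is therefore
*recovery and calibration under the assumed model at a realistic scale* —
not robustness to non-random trap placement, preferential sampling,
observation-time effects or space-time interaction, which real data have
and the generator deliberately omits.

## Numerical and design choices

* Coordinates are projected km; Euclidean distances (a ~10 km extent makes
  curvature negligible). Distance-unit mistakes on prediction grids are
  heuristically detected (all distances > 100× the posterior range) and
  warned about.
* Standardization constants are frozen on the fitting data and re-applied
  to prediction-time covariates; interaction columns are products of
  standardized parents and never re-standardized, so their coefficients
  read as effect modification per SD.
* Weather lags attach to the observation's recorded date (deployment
  vs collection date is not distinguishable in a generic table).
* Kriging prediction uses per-cell conditional means and variances per
  posterior draw; cells are conditionally independent given the sites
  (no joint simulation across cells), which is exact for per-cell maps and
  slightly narrows city-wide *sum* intervals.
* Weekly gridded weather is the mean of daily values within the ISO week,
  with lags applied to the daily series first; predictions assume one
  trap-night per cell-week, and both the sum and the mean across cells are
  reported since either convention is defensible for a "weekly total".
* The posterior-predictive band is pointwise, not simultaneous.
* Sampler determinism: one master seed; chain and stage seeds are fixed
  offsets from it.

## Problem sizes

The bundled analysis scripts and the acceptance script run the recovery
studies at the survey's own scale (51 sites, ~5,100 observations, 2 chains
of 2,600 iterations); the test suite uses 51 sites with ~4,000
observations and shorter adapted chains for the recovery checks, and
20–30-site datasets for unit-level checks. These sizes were chosen so the
posterior standard errors are small relative to the published credible
intervals being used as recovery targets.

## Known limitations

* The Matérn smoothness is fixed at $\nu = 1$; it is not estimated.
* The spatial field is static within a year; seasonal hotspot migration
  is outside the model.
* The selection sampler's mixing for near-collinear candidates relies on
  the Gibbs $\gamma$ step; severe collinearity (|ρ| ≳ 0.9) should be
  resolved upstream (the correlated-pair tooling exists for this).
* DIC is the only comparison criterion, matching standard practice in this
  setting; WAIC/LOO are not provided.

## A minimal run

```{r, eval = FALSE}
library(aedesmapr)

sim <- simulate_scenario(scenario_aegypti(seed = 1),
                         n_sites = 51, mean_obs = 100)
fit <- fit_count_model(sim$data$count, sim$design,
                       sites = sim$data$site_id, coords = sim$layout,
                       family = "negbin", spatial = TRUE,
                       chains = 2, iter = 2600, seed = 2)
print(fit)
pp <- posterior_predictive(fit, n_sims = 1000, seed = 3)
pp$coverage
```

The `analysis/` scripts run the full sequence (simulate → preprocess →
select → fit → validate → predict) and write their tables under
`results/analysis/`.
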