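# aedesmapr

Bayesian spatio-temporal modelling of *Aedes aegypti* and *Aedes
albopictus* trap counts for urban vector surveillance.

Municipal mosquito-control programs run baited traps (e.g. BG-Sentinel)
across a city and count trapped adults per trap-night and species. The
resulting counts are overdispersed, dominated by zeros for rarer species,
sampled unevenly across sites and seasons, and spatially correlated over
sub-kilometre distances because adult *Aedes* disperse less than ~1 km.
`aedesmapr` is for analysts of such programs: it turns a long-format trap
table, per-site covariates and a daily weather series into ranked
predictors, a fitted spatial count model, validation diagnostics and
weekly 1-km risk maps.

## The model

Counts follow a negative-binomial (alternatively Poisson or zero-inflated
Poisson) regression with a log link and a site-level Gaussian spatial
random effect:

    y_i ~ NB(mu_i, n),   log mu_i = beta0 + x_i' beta + u(s_i)
    u   ~ GP(0, C),      C(d) = sigma^2 (kappa d) K_1(kappa d),  kappa = sqrt(8)/rho

Covariates are standardized, so each `beta` is a log incidence-rate ratio
per SD; lag-1/lag-2 weather covariates are the daily values 7/14 days
before the observation. The Matérn range `rho` (correlation ~0.1 at
distance `rho`) and field sd `sigma` carry penalized-complexity priors
calibrated by tail statements (defaults `P(rho < 10 km) = 0.95`,
`P(sigma > 0.5) = 0.05`). Inference is adaptive MCMC over the exact joint
posterior; model choice is by DIC; fit adequacy by the Pearson
overdispersion statistic and a 1,000-draw posterior-predictive simulation
study. Predictor screening uses an NMIG spike-and-slab prior with
posterior inclusion probabilities. A synthetic-data generator reproduces
the statistical structure of a one-year, ~51-site program so the entire
pipeline is testable end to end; see the vignette
(`vignettes/spatial-count-modelling.Rmd`) for the methods.

## Worked example

```r
library(aedesmapr)

sim <- simulate_scenario(scenario_aegypti(seed = 11))   # 51 sites, ~5,100 obs
fit <- fit_count_model(sim$data$count, sim$design,
                       sites = sim$data$site_id, coords = sim$layout,
                       family = "negbin", spatial = TRUE,
                       chains = 2, iter = 2000, seed = 2)
print(fit)
```

```
Bayesian negbin count model + Matern spatial effect: 5102 obs, 1500 draws (2 chains)
Coefficients (posterior mean [95% CI]):
  (Intercept)                   1.590 [ 1.486,  1.694] *
  trees                         0.340 [ 0.309,  0.371] *
  water                        -0.021 [-0.053,  0.011]
  built_pre1979                 0.069 [ 0.037,  0.098] *
  humidity                      0.450 [ 0.419,  0.482] *
  shortwave                     0.525 [ 0.494,  0.556] *
  temperature_lag1             -0.200 [-0.233, -0.170] *
  temperature_lag1:humidity    -0.093 [-0.129, -0.059] *
Hyperparameters (posterior median [95% CI]):
  range_km                      0.785 [ 0.151,  2.190]
  spatial_sd                    0.285 [ 0.227,  0.360]
  nb_size                       0.976 [ 0.930,  1.028]
DIC 27686.33 (pD 51.8); overdispersion 1.02 [0.95, 1.09]
max split-Rhat 1.026
```

The dataset was generated with the abundant-species scenario (intercept
1.59, humidity 0.46, shortwave 0.52, lag-1 temperature −0.21, Matérn range
0.9 km, field sd 0.3, NB size 1): every generating coefficient is inside
its 95% credible interval, starred coefficients have intervals excluding
zero ("statistically important"), and the recovered range matches the
sub-kilometre generating truth. `dic(fit)`, `overdispersion_stat(fit)`,
`posterior_predictive(fit)`, `interpolate_field(fit, grid)` and
`predict_weekly(fit, grid_covariates)` take it from there; the numbered
scripts under `analysis/` run the whole sequence (simulate → preprocess →
select → fit → validate → predict) and write tables under
`results/analysis/`.

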