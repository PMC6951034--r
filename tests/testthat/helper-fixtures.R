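# Shared fixtures, memoised so expensive MCMC fits are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small spatial NB dataset + fit used by validate/predict unit tests
small_sim <- function() cached("small_sim", {
  simulate_scenario(scenario_aegypti(seed = 3), n_sites = 20, mean_obs = 40)
})

small_fit <- function() cached("small_fit", {
  s <- small_sim()
  fit_count_model(s$data$count, s$design, sites = s$data$site_id,
                  coords = s$layout, family = "negbin", spatial = TRUE,
                  chains = 2, iter = 1500, seed = 2,
                  on_nonconvergence = "warn")
})

# non-spatial NB fit on its own generator's data
small_fit_nonspatial <- function() cached("small_fit_nonspatial", {
  s <- small_sim()
  fit_count_model(s$data$count, s$design, family = "negbin", spatial = FALSE,
                  chains = 2, iter = 1500, seed = 2,
                  on_nonconvergence = "warn")
})

# Poisson data + non-spatial Poisson fit (ML-oracle and dispersion checks)
poisson_oracle <- function() cached("poisson_oracle", {
  set.seed(11)
  n <- 5000
  X <- cbind(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  y <- stats::rpois(n, exp(0.5 + 0.4 * X[, 1] - 0.3 * X[, 2]))
  fit <- fit_count_model(y, X, family = "poisson", spatial = FALSE,
                         chains = 2, iter = 1500, seed = 12,
                         on_nonconvergence = "warn")
  glm_fit <- stats::glm(y ~ X[, 1] + X[, 2], family = stats::poisson())
  list(y = y, X = X, fit = fit, glm = glm_fit)
})

# parameter-recovery fits at the surveyed scale (51 sites, ~4000 obs);
# shared between the recovery, range-recovery and predictive-band checks
recovery_fits <- function(scenario_fun, key, n_seeds = 5) cached(key, {
  lapply(seq_len(n_seeds), function(k) {
    sim <- simulate_scenario(scenario_fun(seed = k), n_sites = 51,
                             mean_obs = 80)
    fit_count_model(sim$data$count, sim$design, sites = sim$data$site_id,
                    coords = sim$layout, family = "negbin", spatial = TRUE,
                    chains = 2, iter = 1500, seed = 100 + k,
                    on_nonconvergence = "warn")
  })
})

aegypti_fits <- function() recovery_fits(scenario_aegypti, "aeg_fits")
albopictus_fits <- function() recovery_fits(scenario_albopictus, "albo_fits")

# one fit at the survey's full scale (~5,100 obs), for the range-recovery
# and posterior-predictive checks that are specified at that size
full_scale_fit <- function() cached("full_scale_fit", {
  sim <- simulate_scenario(scenario_aegypti(seed = 1), n_sites = 51,
                           mean_obs = 100)
  fit_count_model(sim$data$count, sim$design, sites = sim$data$site_id,
                  coords = sim$layout, family = "negbin", spatial = TRUE,
                  chains = 2, iter = 2000, seed = 101,
                  on_nonconvergence = "warn")
})

# minimal hand-built trap_fit with a degenerate (point-mass) posterior
degenerate_fit <- function() {
  set.seed(1)
  y <- stats::rpois(50, 3)
  X <- cbind("(Intercept)" = rep(1, 50))
  eta <- rep(log(3), 50)
  dev <- rep(-2 * sum(stats::dpois(y, 3, log = TRUE)), 120)
  structure(list(
    draws = list(beta = matrix(log(3), 120, 1,
                               dimnames = list(NULL, "(Intercept)")),
                 u = NULL, range = rep(1, 120), sd = rep(0, 120),
                 size = rep(1, 120), zi = rep(0, 120), deviance = dev,
                 pearson = rep(1, 120), chain = rep(1:2, each = 60)),
    y = y, X = X, family = "poisson", spatial = FALSE,
    priors = prior_spec(), eta_mean = eta,
    diagnostics = data.frame(param = "(Intercept)", rhat = 1, ess = 120)
  ), class = "trap_fit")
}
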