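# Synthetic trap-data generator: site layouts, daily weather series, and
# count simulation from the spatial count model, so every downstream stage is
# testable without access to the (undeposited) surveillance data.

#' Generate a random trap-site layout
#'
#' Places `n_sites` sites uniformly in a square of side `extent_km` and draws
#' an unbalanced number of observations per site. The default extent of
#' 11.3 km reproduces a mean inter-site distance of ~5.9 km (mean pairwise
#' distance in a unit square is 0.5214, scaled by the side length); per-site
#' observation counts default to mean 100 with a floor of 30, mirroring the
#' retention rule that discards sites with fewer than 30 trap-nights.
#'
#' @param n_sites number of sites (>= 2; spatial covariance is undefined for
#'   a single site).
#' @param extent_km side of the square study extent in km.
#' @param mean_obs,min_obs per-site observation schedule: counts are
#'   `min_obs + Poisson(mean_obs - min_obs)`.
#' @param seed optional integer seed.
#' @return data frame (`site_layout`) with `site_id`, `easting_km`,
#'   `northing_km`, `n_obs`.
#' @export
generate_sites <- function(n_sites = 51, extent_km = 11.3,
                           mean_obs = 100, min_obs = 30, seed = NULL) {
  if (n_sites < 2) stop("need at least 2 sites: spatial covariance undefined")
  stopifnot(extent_km > 0, mean_obs >= min_obs, min_obs >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(
    site_id = sprintf("site%02d", seq_len(n_sites)),
    easting_km = stats::runif(n_sites, 0, extent_km),
    northing_km = stats::runif(n_sites, 0, extent_km),
    n_obs = min_obs + stats::rpois(n_sites, mean_obs - min_obs)
  )
  class(out) <- c("site_layout", "data.frame")
  out
}

#' Generate daily weather series
#'
#' Seasonal sinusoid plus AR(1) noise for daily mean temperature (deg C),
#' water vapour pressure (Pa), shortwave irradiance (W/m^2) and daily total
#' precipitation (mm), loosely emulating a subtropical Gulf-coast climate.
#' The standardized humidity series is the mixture `humid_temp_cor` x
#' standardized temperature + `sqrt(1 - humid_temp_cor^2)` x an independent
#' process whose seasonal phase is a quarter-cycle later (humid early
#' autumn), so the Pearson/Spearman correlation between temperature and
#' humidity is close to `humid_temp_cor` itself: ~0.61 by default and ~0 at
#' 0.
#'
#' @param start_date,end_date `Date`s (or ISO strings); the span must exceed
#'   14 days so lag-2 covariates can be formed.
#' @param humid_temp_cor target temperature-humidity correlation in `[0, 1]`.
#' @param seed optional integer seed.
#' @return data frame with `date`, `temperature`, `humidity`, `shortwave`,
#'   `precipitation`.
#' @export
generate_weather <- function(start_date, end_date, humid_temp_cor = 0.61,
                             seed = NULL) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (as.numeric(end_date - start_date) < 15)
    stop("date span must exceed 14 days (room for lag-2 covariates)")
  stopifnot(humid_temp_cor >= 0, humid_temp_cor <= 1)
  if (!is.null(seed)) set.seed(seed)
  dates <- seq(start_date, end_date, by = "day")
  n <- length(dates)
  doy <- as.numeric(format(dates, "%j"))
  season <- -cospi(2 * (doy - 15) / 365.25)   # min mid-January, max mid-July
  season_late <- -cospi(2 * (doy - 106) / 365.25)  # quarter cycle later
  ar1 <- function(n, phi, sd) {
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
    eps <- stats::rnorm(n, 0, sd)
    for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + eps[i]
    x
  }
  std <- function(x) (x - mean(x)) / stats::sd(x)
  t_raw <- 8 * season + 2.2 * ar1(n, 0.8, 1)
  h_own <- std(8 * season_late + 2.2 * ar1(n, 0.8, 1))
  h_std <- humid_temp_cor * std(t_raw) +
    sqrt(1 - humid_temp_cor^2) * h_own
  temperature <- 23 + t_raw
  humidity <- pmax(400, 2200 + 600 * h_std)   # Pa vapour pressure
  shortwave <- pmax(40, 210 + 90 * season + 35 * ar1(n, 0.6, 1))
  wet <- stats::runif(n) < 0.25
  precipitation <- ifelse(wet, stats::rgamma(n, shape = 0.7, scale = 12), 0)
  data.frame(date = dates, temperature = temperature, humidity = humidity,
             shortwave = shortwave, precipitation = precipitation)
}

#' Configuration for the count generator
#'
#' @param true_beta named numeric vector of generating coefficients on the
#'   log incidence-rate-ratio scale; must include `"(Intercept)"`. Names of
#'   the form `"A:B"` denote interaction columns formed as elementwise
#'   products of the standardized parents.
#' @param family generating family.
#' @param true_range_km,true_sd Matern range (km) and marginal sd of the
#'   site-level spatial field (smoothness fixed at 1).
#' @param nb_size negative-binomial size; `zip_prob` zero-inflation
#'   probability.
#' @param seed integer seed; the same config (including seed) reproduces the
#'   dataset bit for bit.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(true_beta, family = c("negbin", "poisson", "zip"),
                             true_range_km = 0.9, true_sd = 0.3,
                             nb_size = 1, zip_prob = 0, seed = 1L) {
  family <- match.arg(family)
  stopifnot(is.numeric(true_beta), "(Intercept)" %in% names(true_beta),
            true_range_km > 0, true_sd >= 0, nb_size > 0,
            zip_prob >= 0, zip_prob < 1)
  structure(list(true_beta = true_beta, family = family,
                 true_range_km = true_range_km, true_sd = true_sd,
                 nb_size = nb_size, zip_prob = zip_prob,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generating truth for the abundant-species scenario
#'
#' Coefficients on the standardized log-IRR scale for the high-count species
#' (*Aedes aegypti*-like): positive tree cover, humidity and shortwave
#' effects, a negative 1-week-lagged temperature effect and a negative
#' temperature-by-humidity interaction; Matern range 0.9 km. With NB size 1
#' the marginal zero fraction is close to one count in five or six.
#' @param seed integer seed stored in the config.
#' @return `generator_config`
#' @export
scenario_aegypti <- function(seed = 1L) {
  beta <- c("(Intercept)" = 1.59, trees = 0.34, water = -0.01,
            built_pre1979 = 0.09, humidity = 0.46, shortwave = 0.52,
            temperature_lag1 = -0.21, "temperature_lag1:humidity" = -0.08)
  generator_config(beta, family = "negbin", true_range_km = 0.9,
                   true_sd = 0.3, nb_size = 1, seed = seed)
}

#' Generating truth for the rare-species scenario
#'
#' Low-intercept (*Aedes albopictus*-like) scenario: strong negative
#' population-density and lag-1 temperature effects, positive lag-2 humidity
#' effect, interactions as in the abundant-species scenario; Matern range
#' 1.0 km. The marginal zero fraction is well above 50%.
#' @param seed integer seed stored in the config.
#' @return `generator_config`
#' @export
scenario_albopictus <- function(seed = 1L) {
  beta <- c("(Intercept)" = -1.50, impervious = -0.41, grass = -0.25,
            built_pre1969 = 0.00, pop_density = -0.80,
            humidity_lag2 = 0.55, temperature_lag1 = -0.50,
            "impervious:grass" = 0.42,
            "temperature_lag1:humidity_lag2" = -0.13)
  generator_config(beta, family = "negbin", true_range_km = 1.0,
                   true_sd = 0.3, nb_size = 1, seed = seed)
}

# Expand a named truth vector into a model matrix of iid standard-normal
# main-effect columns plus product interaction columns.
.design_from_truth <- function(n, true_beta) {
  terms <- setdiff(names(true_beta), "(Intercept)")
  mains <- terms[!grepl(":", terms, fixed = TRUE)]
  inter <- terms[grepl(":", terms, fixed = TRUE)]
  X <- matrix(stats::rnorm(n * length(mains)), n, length(mains),
              dimnames = list(NULL, mains))
  for (ab in inter) {
    pa <- strsplit(ab, ":", fixed = TRUE)[[1]]
    if (!all(pa %in% mains)) stop("interaction parents missing: ", ab)
    X <- cbind(X, X[, pa[1]] * X[, pa[2]])
    colnames(X)[ncol(X)] <- ab
  }
  X
}

#' Simulate trap counts from the spatial count model
#'
#' Draws one site-level spatial field \eqn{u \sim GP(0,
#' Matern(\rho, \sigma, \nu = 1))} per dataset, forms the linear predictor
#' \eqn{\log\mu_i = \beta_0 + x_i^T\beta + u(s_i)} and draws counts from the
#' configured family. The design matrix may be supplied; by default
#' iid standard-normal columns matching the truth's names are generated
#' (covariates enter the model standardized, and their raw-scale
#' distributions are unknowable, so the generator works directly on the
#' standardized scale).
#'
#' @param layout a `site_layout` from [generate_sites()].
#' @param config a [generator_config()].
#' @param design optional numeric matrix with one row per observation and
#'   columns named after the non-intercept truth terms.
#' @param dates optional vector of `Date`s to sample observation dates from;
#'   default the days of 2017.
#' @return list with `data` (long table: `site_id`, `easting_km`,
#'   `northing_km`, `date`, `count`, plus the design columns), `design`
#'   (matrix), `u` (true field), `eta` (true linear predictor) and `config`.
#' @export
simulate_counts <- function(layout, config, design = NULL, dates = NULL) {
  stopifnot(inherits(layout, "site_layout"), inherits(config, "generator_config"))
  set.seed(config$seed)
  S <- nrow(layout)
  n <- sum(layout$n_obs)
  site_idx <- rep(seq_len(S), layout$n_obs)
  if (is.null(dates))
    dates <- seq(as.Date("2017-01-01"), as.Date("2017-12-31"), by = "day")
  obs_date <- sort(sample(dates, n, replace = TRUE))
  obs_date <- obs_date[order(stats::runif(n))][order(site_idx)]

  if (is.null(design)) design <- .design_from_truth(n, config$true_beta)
  terms <- setdiff(names(config$true_beta), "(Intercept)")
  if (!all(terms %in% colnames(design)))
    stop("design lacks columns: ",
         paste(setdiff(terms, colnames(design)), collapse = ", "))

  u <- if (config$true_sd > 0) {
    D <- site_distances(layout[, c("easting_km", "northing_km")])
    C <- matern_cov(D, config$true_range_km, config$true_sd)
    drop(crossprod(chol(C), stats::rnorm(S)))
  } else rep(0, S)

  eta <- config$true_beta[["(Intercept)"]] +
    drop(design[, terms, drop = FALSE] %*% config$true_beta[terms]) +
    u[site_idx]
  if (any(!is.finite(eta))) {
    bad <- which(!is.finite(eta))[1]
    stop("non-finite linear predictor at row ", bad)
  }
  y <- count_simulate(n, exp(eta), family = config$family,
                      size = config$nb_size, zi = config$zip_prob)
  dat <- data.frame(
    site_id = layout$site_id[site_idx],
    easting_km = layout$easting_km[site_idx],
    northing_km = layout$northing_km[site_idx],
    date = obs_date,
    count = y
  )
  dat <- cbind(dat, as.data.frame(design))
  list(data = dat, design = design, u = u, eta = eta, config = config,
       layout = layout)
}

#' One-call scenario dataset
#'
#' Convenience wrapper: generates a site layout and simulates counts for a
#' scenario config, deriving the layout seed from the config seed.
#' @param config a [generator_config()], e.g. [scenario_aegypti()].
#' @param n_sites,extent_km,mean_obs layout parameters.
#' @return as [simulate_counts()].
#' @export
simulate_scenario <- function(config, n_sites = 51, extent_km = 11.3,
                              mean_obs = 100) {
  layout <- generate_sites(n_sites, extent_km, mean_obs,
                           seed = config$seed + 1000L)
  simulate_counts(layout, config)
}
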